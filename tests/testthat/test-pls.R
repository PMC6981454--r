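# PLS regression, LOO cross-validation and model statistics, checked
# against closed forms and independent brute-force oracles.

test_that("IC50 to pIC50 conversion and censoring guard", {
  expect_equal(ic50_to_pic50(1.0), 6.0)
  expect_equal(ic50_to_pic50(0.40), 6.39794, tolerance = 1e-5)
  expect_error(ic50_to_pic50(25, censored = TRUE), "censored")
  expect_error(ic50_to_pic50(-1), "positive")
})

test_that("full-rank PLS reproduces least-squares predictions", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12; p <- 4
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    model <- fit_pls(X, y, ncomp = p)
    # oracle: ordinary least squares on centered data
    ols <- stats::lm.fit(cbind(1, X), y)
    expect_equal(predict(model, X), as.vector(cbind(1, X) %*% ols$coefficients),
                 tolerance = 1e-8)
  }
})

test_that("univariate PLS with one component is simple regression", {
  set.seed(7)
  x <- matrix(rnorm(15), ncol = 1)
  y <- 2.5 * x[, 1] + rnorm(15, 0, 0.3)
  model <- fit_pls(x, y, 1)
  slope <- stats::cov(x[, 1], y) / stats::var(x[, 1])
  expect_equal(model$b[1], slope, tolerance = 1e-10)
  expect_equal(model$intercept, mean(y) - slope * mean(x), tolerance = 1e-10)
})

test_that("constant response yields the zero model with mean intercept", {
  X <- matrix(rnorm(20), 5, 4)
  y <- rep(3.2, 5)
  model <- fit_pls(X, y, 2)
  expect_equal(model$b, rep(0, 4))
  expect_equal(model$intercept, 3.2)
})

test_that("requesting more components than the rank supports errors", {
  X <- cbind(1:6, (1:6) * 2) # rank 1 after centering
  y <- rnorm(6)
  expect_error(fit_pls(X, y, 3), "rank|exhausted")
})

test_that("LOO q2 is exact on collinear data and matches the refit oracle", {
  x <- matrix(seq_len(8), ncol = 1)
  y <- 3 * x[, 1] - 1
  expect_equal(loo_q2(x, y, 1)$q2, 1, tolerance = 1e-10)

  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rnorm(10 * 8), 10, 8)
    y <- rnorm(10)
    got <- loo_q2(X, y, 2)
    # independent naive loop, refitting from scratch per fold
    pred <- vapply(1:10, function(i) {
      predict(fit_pls(X[-i, ], y[-i], 2), X[i, , drop = FALSE])
    }, 0)
    q2 <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
    expect_equal(got$predictions, pred, tolerance = 1e-12)
    expect_equal(got$q2, q2, tolerance = 1e-12)
  }
  expect_error(loo_q2(matrix(rnorm(12), 6, 2), rep(1, 6), 1), "constant")
})

test_that("LOO predictions never beat resubstitution: q2 <= r2", {
  set.seed(5)
  for (rep in 1:8) {
    n <- 10 + rep
    X <- matrix(rnorm(n * 6), n, 6)
    y <- X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.5)
    k <- sample(1:3, 1)
    model <- fit_pls(X, y, k)
    stats <- final_stats(model, X, y)
    expect_lte(stats$q2, stats$r2 + 1e-12)
  }
})

test_that("component selection honours the floor(n/3) cap and tie rule", {
  set.seed(3)
  # single latent factor, no noise: one component suffices
  t1 <- rnorm(15)
  X <- outer(t1, rnorm(10))
  y <- 2 * t1
  sel <- select_components(X, y, n_max = 5)
  expect_equal(sel$ncomp, 1L)
  expect_gt(sel$q2, 0.999)
  # n = 9 rows -> search capped at 3 components
  X9 <- matrix(rnorm(9 * 6), 9, 6)
  y9 <- rnorm(9)
  sel9 <- select_components(X9, y9, n_max = 10)
  expect_lte(length(sel9$q2_by_ncomp), 3L)
})

test_that("train/test splits match the published sizes and guards", {
  s20 <- split_train_test(sprintf("c%02d", 1:20), fraction = 0.75, seed = 1)
  expect_length(s20$train, 15)
  expect_length(s20$test, 5)
  s14 <- split_train_test(sprintf("c%02d", 1:14), fraction = 0.71, seed = 1)
  expect_length(s14$train, 10)
  expect_length(s14$test, 4)
  s10 <- split_train_test(sprintf("c%02d", 1:10), fraction = 0.999, seed = 1)
  expect_length(s10$test, 1)
  expect_identical(split_train_test(letters[1:8], 0.75, seed = 99),
                   split_train_test(letters[1:8], 0.75, seed = 99))
  expect_error(
    split_train_test(letters[1:4], train = c("a", "b"), test = c("b", "c", "d")),
    "overlap")
  expect_error(
    split_train_test(letters[1:4], train = c("a"), test = c("b", "c")),
    "partition")
})

test_that("external validation statistics follow the PRESS/SD arithmetic", {
  X_train <- matrix(c(-1, 0, 1), ncol = 1)
  y_train <- c(1.1, 2.0, 2.9)
  model <- fit_pls(X_train, y_train, 1) # slope 0.9, intercept 2 exactly
  X_test <- matrix(c(-1, 0, 1), ncol = 1)
  y_test <- c(1, 2, 3)
  st <- final_stats(model, X_train, y_train, X_test, y_test, q2 = 0)
  expect_equal(st$sd, 2)
  expect_equal(st$press, 0.02, tolerance = 1e-12)
  expect_equal(st$r2_pred, 0.99, tolerance = 1e-12)
  # perfect predictions give r2pred = 1
  st2 <- final_stats(model, X_train, y_train, X_test, c(1.1, 2.0, 2.9), q2 = 0)
  expect_equal(st2$r2_pred, 1)
  # predicting the training mean gives r2pred = 0
  flat <- fit_pls(X_train, rep(2, 3), 1)
  st3 <- final_stats(flat, X_train, y_train, X_test, y_test, q2 = 0)
  expect_equal(st3$r2_pred, 0)
  # no test set: external stats absent, not zero
  st4 <- final_stats(model, X_train, y_train, q2 = 0)
  expect_null(st4$r2_pred)
})

test_that("field contributions split by block and sum to one", {
  set.seed(8)
  X <- matrix(rnorm(12 * 6), 12, 6)
  colnames(X) <- c(paste0("S:", 0:2), paste0("E:", 0:2))
  y <- X[, 1] + rnorm(12, 0, 0.1)
  model <- fit_pls(X, y, 2)
  st <- final_stats(model, X, y)
  expect_equal(st$steric_fraction + st$electrostatic_fraction, 1,
               tolerance = 1e-9)
  expect_gt(st$steric_fraction, st$electrostatic_fraction)
})
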