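# Partial least squares regression (NIPALS), leave-one-out cross-validation
# and the CoMFA model statistics: q2, r2, SEE, r2pred, field contributions.

#' Convert IC50 (micromolar) to pIC50
#'
#' pIC50 = -log10(IC50 in molar) = -log10(ic50_um * 1e-6).
#'
#' @param ic50_um positive IC50 value(s) in micromolar.
#' @param censored logical flag(s); censored values (">X") have no pIC50 and
#'   raise an error.
#' @return pIC50 value(s).
#' @examples
#' ic50_to_pic50(1)    # 6
#' ic50_to_pic50(0.40) # 6.398
#' @export
ic50_to_pic50 <- function(ic50_um, censored = FALSE) {
  if (any(censored)) stop("censored value has no pIC50")
  if (any(!is.finite(ic50_um) | ic50_um <= 0)) stop("IC50 must be positive")
  -log10(ic50_um * 1e-6)
}

#' Fit a PLS regression model (NIPALS)
#'
#' Sequential latent components on column-centered data, maximizing the
#' covariance between X scores and y. Deterministic; no scaling is applied
#' (CoMFA fields are already in common energy units).
#'
#' @param X numeric matrix (n x p).
#' @param y numeric response vector (length n).
#' @param ncomp number of latent components.
#' @return a `pls_model`: centering vectors, weights `W`, loadings `P`,
#'   y-loadings `q`, scores `T`, regression vector `b` and `intercept`.
#' @export
fit_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncomp >= 1)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  n <- nrow(X); p <- ncol(X)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      if (a == 1L) { # constant y: zero model
        b <- numeric(p)
        return(structure(list(
          ncomp = 0L, x_mean = x_mean, y_mean = y_mean,
          W = W, P = P, q = q, scores = Tm, b = b, intercept = y_mean,
          colnames = colnames(X)
        ), class = "pls_model"))
      }
      stop("requested ", ncomp, " components but X/y covariance is exhausted at ", a - 1L)
    }
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) stop("component ", a, " exceeds the rank of X")
    pvec <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pvec)
    yc <- yc - qa * t
    W <- cbind(W, w); P <- cbind(P, pvec); Tm <- cbind(Tm, t); q <- c(q, qa)
  }
  R <- W %*% solve(crossprod(P, W))
  b <- as.vector(R %*% q)
  structure(list(
    ncomp = ncomp, x_mean = x_mean, y_mean = y_mean,
    W = W, P = P, q = q, scores = Tm, b = b,
    intercept = y_mean - sum(x_mean * b), colnames = colnames(X)
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d component(s), %d predictors>\n",
    x$ncomp, length(x$b)))
  invisible(x)
}

#' Predict from a PLS model
#' @param object a `pls_model`.
#' @param newdata matrix of predictors (n x p).
#' @param ... unused.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.vector(newdata %*% object$b) + object$intercept
}

#' Leave-one-out cross-validated q2
#'
#' For each observation i, a model with `ncomp` components is refit on the
#' remaining rows and used to predict y_i. q2 = 1 - PRESS / sum((y - ybar)^2)
#' with ybar the full-sample mean by default (`mean = "fold"` uses each
#' training fold's own mean instead).
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param ncomp number of components.
#' @param mean `"full"` or `"fold"`: which mean anchors the q2 denominator.
#' @return list(q2, predictions).
#' @export
loo_q2 <- function(X, y, ncomp, mean = c("full", "fold")) {
  mean <- match.arg(mean)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, length(y) == n)
  if (stats::sd(y) < 1e-12) stop("constant response: q2 undefined")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
  }
  ybar <- if (mean == "full") base::mean(y) else NULL
  denom <- if (mean == "full") {
    sum((y - ybar)^2)
  } else {
    sum(vapply(seq_len(n), function(i) (y[i] - base::mean(y[-i]))^2, 0))
  }
  list(q2 = 1 - sum((y - pred)^2) / denom, predictions = pred)
}

#' Select the number of PLS components by LOO q2
#'
#' Searches N = 1..min(n_max, floor(n/3)) (the "components < 33.3% of the
#' compounds" quality rule applied as a hard cap) and returns the N
#' maximizing leave-one-out q2; ties go to the smaller N.
#'
#' @inheritParams loo_q2
#' @param n_max upper bound on the number of components.
#' @return list(ncomp, q2, q2_by_ncomp).
#' @export
select_components <- function(X, y, n_max = 10L, mean = "full") {
  n <- nrow(as.matrix(X))
  cap <- min(n_max, max(1L, floor(n / 3)))
  q2s <- rep(NA_real_, cap)
  for (k in seq_len(cap)) {
    q2s[k] <- tryCatch(loo_q2(X, y, k, mean = mean)$q2,
                       error = function(e) NA_real_)
  }
  if (all(is.na(q2s))) stop("no valid component count in 1..", cap)
  best <- which.max(q2s)
  list(ncomp = best, q2 = q2s[best], q2_by_ncomp = q2s)
}

#' Split compounds into training and test sets
#'
#' Reproducible random split: `round(fraction * n)` compounds to the
#' training set (guarded so that at least one compound remains in each
#' set), the remainder to the test set. Explicit id lists may be given
#' instead.
#'
#' @param ids character vector of compound ids.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed (only the split consumes it; the global RNG
#'   state is restored afterwards).
#' @param train,test optional explicit id vectors partitioning `ids`.
#' @return list(train, test) of id vectors.
#' @export
split_train_test <- function(ids, fraction = 0.75, seed = 20191225L,
                             train = NULL, test = NULL) {
  if (!is.null(train) || !is.null(test)) {
    if (length(intersect(train, test))) stop("train and test sets overlap")
    if (!setequal(c(train, test), ids)) {
      stop("explicit train/test lists must partition the ids")
    }
    return(list(train = train, test = test))
  }
  stopifnot(fraction > 0, fraction < 1, length(ids) >= 2)
  n <- length(ids)
  n_train <- min(max(round(fraction * n), 1L), n - 1L)
  perm <- .with_seed(seed, sample(ids))
  list(train = sort(perm[seq_len(n_train)]), test = sort(perm[-seq_len(n_train)]))
}

# Evaluate expr under a temporary RNG seed, restoring the global state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Final CoMFA model statistics
#'
#' Internal statistics on the training set (r2 = 1 - RSS/TSS, SEE =
#' sqrt(RSS/(n - N - 1)), LOO q2) and external validation on the test set:
#' r2pred = (SD - PRESS) / SD, where SD is the sum of squared deviations of
#' the test activities from the training mean and PRESS the sum of squared
#' test prediction errors. Field contributions are the block sums of
#' |coefficient| x column standard deviation, normalized to 1.
#'
#' @param model a `pls_model` fitted on the training block.
#' @param X_train,y_train training predictors/response.
#' @param X_test,y_test test predictors/response (optional; `r2_pred`,
#'   `press` and `sd` are absent when no test set is supplied).
#' @param q2 optionally, a precomputed LOO q2 (recomputed if `NULL`).
#' @param mean q2 mean convention, see [loo_q2()].
#' @return a `model_stats` list: q2, r2, see, n_components, r2_pred, press,
#'   sd, steric_fraction, electrostatic_fraction.
#' @export
final_stats <- function(model, X_train, y_train, X_test = NULL, y_test = NULL,
                        q2 = NULL, mean = "full") {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  fitted <- predict(model, X_train)
  rss <- sum((y_train - fitted)^2)
  tss <- sum((y_train - base::mean(y_train))^2)
  r2 <- 1 - rss / tss
  see <- sqrt(rss / max(n - model$ncomp - 1, 1))
  if (is.null(q2)) q2 <- loo_q2(X_train, y_train, model$ncomp, mean = mean)$q2
  cn <- model$colnames
  if (is.null(cn)) cn <- colnames(X_train)
  contrib <- abs(model$b) * apply(X_train, 2, stats::sd)
  steric <- sum(contrib[grepl("^S:", cn)])
  electro <- sum(contrib[grepl("^E:", cn)])
  tot <- steric + electro
  out <- list(
    q2 = q2, r2 = r2, see = see, n_components = model$ncomp,
    steric_fraction = if (tot > 0) steric / tot else NA_real_,
    electrostatic_fraction = if (tot > 0) electro / tot else NA_real_
  )
  if (!is.null(X_test) && nrow(as.matrix(X_test)) > 0) {
    X_test <- as.matrix(X_test)
    pred <- predict(model, X_test)
    press <- sum((y_test - pred)^2)
    sd_ <- sum((y_test - base::mean(y_train))^2)
    out$press <- press
    out$sd <- sd_
    out$r2_pred <- (sd_ - press) / sd_
  }
  structure(out, class = "model_stats")
}

#' @export
print.model_stats <- function(x, ...) {
  cat(sprintf("q2 = %.3f  r2 = %.3f  SEE = %.3f  N = %d\n",
    x$q2, x$r2, x$see, x$n_components))
  if (!is.null(x$r2_pred)) cat(sprintf("r2pred = %.3f  (PRESS = %.3f, SD = %.3f)\n",
    x$r2_pred, x$press, x$sd))
  cat(sprintf("field contributions: steric %.1f%%, electrostatic %.1f%%\n",
    100 * x$steric_fraction, 100 * x$electrostatic_fraction))
  invisible(x)
}
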