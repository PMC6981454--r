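# Lattice construction and Lennard-Jones / Coulomb field evaluation.

one_atom <- function(el = "C", pos = c(0, 0, 0), charge = 0, id = "atom") {
  fake_molecule(id, el, matrix(pos, 1, 3), charge = charge)
}

test_that("grid construction follows the extent/margin arithmetic", {
  m <- one_atom()
  g <- build_grid(fake_aligned(list(m)), spacing = 2, margin = 4)
  expect_equal(g$counts, c(5L, 5L, 5L))
  expect_equal(nrow(g$points), 125L)
  g0 <- build_grid(fake_aligned(list(m)), spacing = 2, margin = 0)
  expect_equal(g0$counts, c(1L, 1L, 1L))
  expect_equal(as.numeric(g0$points), c(0, 0, 0))
  expect_error(build_grid(list()), "empty")
  # defaults are the standard CoMFA settings
  expect_equal(formals(build_grid)$spacing, 2.0)
})

test_that("steric energy decays, truncates, and hits the analytic minimum", {
  m <- one_atom("C")
  expect_lt(abs(steric_energy(m, c(50, 0, 0))), 1e-3)
  expect_identical(steric_energy(m, c(0, 0, 0)), 30.0)
  # at r = r_C + r_probe the 6-12 potential equals -sqrt(eps_C * eps_probe)
  probe <- probe_spec()
  rmin <- 1.70 + probe$vdw_radius
  eps <- sqrt(0.107 * probe$well_depth)
  expect_equal(steric_energy(m, c(rmin, 0, 0)), -eps, tolerance = 1e-12)
})

test_that("electrostatic energy has Coulomb sign, form and clamping", {
  neutral <- one_atom("C", charge = 0)
  expect_equal(electrostatic_energy(neutral, c(1, 0, 0)), 0)
  neg <- one_atom("O", charge = -0.5)
  expect_lt(electrostatic_energy(neg, c(2, 0, 0)), 0)
  expect_equal(abs(electrostatic_energy(neg, c(0, 0, 0))), 30)
  # k q qp / r^2 with distance-dependent dielectric eps(r) = r
  q <- 0.3; r <- 2.5
  mol <- one_atom("N", charge = q)
  expect_equal(electrostatic_energy(mol, c(r, 0, 0)),
               332.0637 * q / r^2, tolerance = 1e-9)
})

test_that("fields match a brute-force oracle on a tiny grid", {
  m <- one_atom("N", pos = c(0.3, -0.2, 0.5), charge = -0.4)
  g <- build_grid(fake_aligned(list(m)), spacing = 1.5, margin = 1.5)
  probe <- probe_spec()
  brute_lj <- function(p) {
    r <- sqrt(sum((p - c(0.3, -0.2, 0.5))^2))
    rm <- 1.55 + probe$vdw_radius
    eps <- sqrt(0.095 * probe$well_depth)
    min(eps * ((rm / r)^12 - 2 * (rm / r)^6), 30)
  }
  brute_coul <- function(p) {
    r <- sqrt(sum((p - c(0.3, -0.2, 0.5))^2))
    max(min(332.0637 * (-0.4) / r^2, 30), -30)
  }
  got_s <- steric_energy(m, g$points, probe)
  got_e <- electrostatic_energy(m, g$points, probe)
  exp_s <- apply(g$points, 1, brute_lj)
  exp_e <- apply(g$points, 1, brute_coul)
  expect_equal(got_s, exp_s, tolerance = 1e-9)
  expect_equal(got_e, exp_e, tolerance = 1e-9)
})

test_that("field matrix has block shape, duplicates and truncation bounds", {
  m1 <- fake_molecule("m1", c("C", "N"),
                      rbind(c(0, 0, 0), c(1.4, 0, 0)), charge = c(0.2, -0.2))
  m2 <- m1; m2$id <- "m2"
  al <- fake_aligned(list(m1, m2))
  g <- build_grid(al, spacing = 2, margin = 4)
  fm <- compute_field_matrix(al, g)
  expect_equal(dim(field_values(fm, filtered = FALSE)),
               c(2L, 2L * nrow(g$points)))
  expect_equal(fm$steric["m1", ], fm$steric["m2", ])
  expect_equal(fm$electrostatic["m1", ], fm$electrostatic["m2", ])
  expect_lte(max(fm$steric), 30)
  expect_lte(max(abs(fm$electrostatic)), 30)
})

test_that("co-translating molecules and grid leaves the matrix unchanged", {
  m <- fake_molecule("m", c("C", "O"),
                     rbind(c(0, 0, 0), c(1.2, 0.3, -0.5)),
                     charge = c(0.25, -0.25))
  al <- fake_aligned(list(m))
  g <- build_grid(al, spacing = 2, margin = 3)
  fm <- compute_field_matrix(al, g)
  shift <- c(7.3, -2.1, 4.4)
  m2 <- comfa:::.transform_molecule(m, diag(3), shift)
  al2 <- fake_aligned(list(m2))
  g2 <- g
  g2$origin <- g$origin + shift
  g2$points <- sweep(g$points, 2, shift, `+`)
  fm2 <- compute_field_matrix(al2, g2)
  expect_equal(unname(fm2$steric), unname(fm$steric), tolerance = 1e-9)
  expect_equal(unname(fm2$electrostatic), unname(fm$electrostatic),
               tolerance = 1e-9)
})

test_that("molecules outside the grid are refused", {
  m <- one_atom()
  far <- one_atom(pos = c(100, 0, 0), id = "far")
  g <- build_grid(fake_aligned(list(m)), spacing = 2, margin = 4)
  expect_error(compute_field_matrix(fake_aligned(list(m, far)), g), "far")
})

test_that("sterically excluded points take the column-mean electrostatics", {
  # one molecule clashes with a grid node the other leaves free
  m1 <- one_atom("C", pos = c(0, 0, 0), charge = 0.5, id = "m1")
  m2 <- one_atom("C", pos = c(2, 0, 0), charge = 0.5, id = "m2")
  al <- fake_aligned(list(m1, m2))
  g <- build_grid(al, spacing = 2, margin = 2)
  fm_raw <- compute_field_matrix(al, g, exclude_electrostatic = FALSE)
  fm <- compute_field_matrix(al, g, exclude_electrostatic = TRUE)
  clash <- fm$steric >= 30
  expect_true(any(clash))
  j <- which(clash["m1", ] & !clash["m2", ])[1]
  expect_equal(fm$electrostatic["m1", j], fm_raw$electrostatic["m2", j])
})

test_that("column filter drops exactly the low-spread columns", {
  m1 <- one_atom(id = "a"); m2 <- one_atom(id = "b")
  al <- fake_aligned(list(m1, m2))
  g <- build_grid(al, spacing = 2, margin = 2)
  fm <- compute_field_matrix(al, g)
  # identical rows -> all columns constant -> everything dropped
  expect_error(column_filter(fm, 2), "no variance")
  fm0 <- column_filter(fm, 0)
  expect_true(all(fm0$kept))
  expect_equal(formals(column_filter)$threshold, 2.0)
})
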