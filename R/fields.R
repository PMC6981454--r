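# CoMFA molecular interaction fields: steric (Lennard-Jones 6-12) and
# electrostatic (Coulomb, distance-dependent dielectric) energies of a probe
# atom at every node of a cubic lattice enclosing the aligned set.

#' Probe atom specification
#'
#' The classic CoMFA probe: an sp3 carbon with van der Waals radius 1.52 A,
#' charge +1.0 e and well depth 0.107 kcal/mol.
#'
#' @param vdw_radius probe van der Waals radius in Angstrom.
#' @param charge probe charge in elementary charges.
#' @param well_depth Lennard-Jones well depth in kcal/mol.
#' @return a `probe_spec` list.
#' @export
probe_spec <- function(vdw_radius = 1.52, charge = 1.0, well_depth = 0.107) {
  stopifnot(vdw_radius > 0, well_depth > 0)
  structure(list(vdw_radius = vdw_radius, charge = charge,
                 well_depth = well_depth), class = "probe_spec")
}

# Per-element Lennard-Jones well depths (kcal/mol), Tripos-style values.
.lj_epsilon <- c(
  H = 0.042, C = 0.107, N = 0.095, O = 0.116, F = 0.109,
  Cl = 0.314, S = 0.314, P = 0.314, Br = 0.434, I = 0.623
)

.coulomb_k <- 332.0637 # kcal A / (mol e^2)

#' Build a cubic lattice around an aligned set
#'
#' Axis-aligned box enclosing every atom of every molecule with at least
#' `margin` clearance, spacing `spacing` per axis. The origin is anchored at
#' `floor(min - margin)` per axis so grids are reproducible across runs.
#'
#' @param aligned an `aligned_set`, or a list of `molecule` objects.
#' @param spacing grid spacing in Angstrom (default 2.0).
#' @param margin clearance around the atoms in Angstrom (default 4.0).
#' @return a `grid_spec`: list(origin, spacing, counts, margin, points)
#'   where `points` is the (prod(counts) x 3) matrix of node coordinates in
#'   x-fastest order.
#' @export
build_grid <- function(aligned, spacing = 2.0, margin = 4.0) {
  stopifnot(spacing > 0, margin >= 0)
  mols <- if (inherits(aligned, "aligned_set")) aligned$molecules else aligned
  if (!length(mols)) stop("empty aligned set")
  xyz <- do.call(rbind, lapply(mols, coords))
  lo <- floor(apply(xyz, 2, min) - margin)
  hi <- apply(xyz, 2, max) + margin
  counts <- pmax(1L, as.integer(floor((hi - lo) / spacing)) + 1L)
  ax <- lapply(1:3, function(k) lo[k] + spacing * (seq_len(counts[k]) - 1L))
  points <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                  KEEP.OUT.ATTRS = FALSE))
  structure(list(origin = lo, spacing = spacing, counts = counts,
                 margin = margin, points = points), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec: %dx%dx%d nodes, spacing %.2f A, origin (%g, %g, %g)>\n",
    x$counts[1], x$counts[2], x$counts[3], x$spacing,
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# Distance matrix between grid points (p x 3) and atoms (m x 3).
.point_atom_dist <- function(points, xyz) {
  d2 <- outer(rowSums(points^2), rowSums(xyz^2), `+`) -
    2 * points %*% t(xyz)
  sqrt(pmax(d2, 0))
}

#' Steric (Lennard-Jones 6-12) probe energy
#'
#' Sum over atoms of eps_ij \[(R/r)^12 - 2 (R/r)^6\] with R = r_atom +
#' r_probe (minimum-energy distance) and eps_ij the geometric mean of the
#' atom and probe well depths, truncated at `+cutoff`.
#'
#' @param mol a `molecule` with vdW radii assigned.
#' @param points one 3-vector or an (n x 3) matrix of probe positions (A).
#' @param probe a [probe_spec()].
#' @param cutoff truncation energy in kcal/mol (default 30).
#' @return energies in kcal/mol, one per point.
#' @export
steric_energy <- function(mol, points, probe = probe_spec(), cutoff = 30.0) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- .point_atom_dist(points, coords(mol))
  rmin <- mol$atoms$vdw + probe$vdw_radius
  eps <- sqrt(.lj_epsilon[mol$atoms$element] * probe$well_depth)
  s6 <- sweep(1 / pmax(r, 1e-12), 2, rmin, `*`)^6
  e <- rowSums(sweep(s6^2 - 2 * s6, 2, eps, `*`))
  pmin(e, cutoff)
}

#' Electrostatic (Coulomb) probe energy
#'
#' Sum over atoms of k q_i q_probe / (eps(r) r) with the distance-dependent
#' dielectric eps(r) = r, i.e. k q_i q_probe / r^2, k = 332.0637
#' kcal A mol^-1 e^-2; clamped to \[-cutoff, +cutoff\].
#'
#' @inheritParams steric_energy
#' @export
electrostatic_energy <- function(mol, points, probe = probe_spec(),
                                 cutoff = 30.0) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  r <- .point_atom_dist(points, coords(mol))
  e <- .coulomb_k * probe$charge *
    rowSums(sweep(1 / pmax(r, 1e-12)^2, 2, mol$atoms$charge, `*`))
  pmin(pmax(e, -cutoff), cutoff)
}

#' Compute the CoMFA field matrix
#'
#' One row per molecule; the steric block (columns `S:<i>`) followed by the
#' electrostatic block (`E:<i>`), `i` being the 0-based x-fastest grid node
#' index. Electrostatic values at sterically excluded nodes (steric energy
#' at the cutoff) are replaced by the column mean over the non-clashing
#' molecules - the standard CoMFA convention - unless
#' `exclude_electrostatic = FALSE`.
#'
#' @param aligned an `aligned_set`.
#' @param grid a `grid_spec` from [build_grid()].
#' @param probe a [probe_spec()].
#' @param cutoff truncation energy, kcal/mol.
#' @param exclude_electrostatic replace electrostatic values at sterically
#'   excluded nodes by the column mean of non-clashing molecules.
#' @return a `field_matrix`: list(ids, steric, electrostatic, grid, probe,
#'   cutoff, kept, threshold). `kept` is a logical mask over the combined
#'   columns, set by [column_filter()] (initially all TRUE).
#' @export
compute_field_matrix <- function(aligned, grid = build_grid(aligned),
                                 probe = probe_spec(), cutoff = 30.0,
                                 exclude_electrostatic = TRUE) {
  mols <- aligned$molecules
  ids <- names(mols)
  lo <- grid$origin
  hi <- lo + (grid$counts - 1L) * grid$spacing
  for (m in mols) {
    xyz <- coords(m)
    if (any(sweep(xyz, 2, lo, `<`)) || any(sweep(xyz, 2, hi, `>`))) {
      stop("molecule '", m$id, "' lies outside the grid box")
    }
  }
  S <- t(vapply(mols, steric_energy, numeric(nrow(grid$points)),
                points = grid$points, probe = probe, cutoff = cutoff))
  E <- t(vapply(mols, electrostatic_energy, numeric(nrow(grid$points)),
                points = grid$points, probe = probe, cutoff = cutoff))
  if (isTRUE(exclude_electrostatic)) {
    clash <- S >= cutoff
    for (j in which(colSums(clash) > 0)) {
      ok <- !clash[, j]
      E[!ok, j] <- if (any(ok)) mean(E[ok, j]) else 0
    }
  }
  idx <- seq_len(nrow(grid$points)) - 1L
  dimnames(S) <- list(ids, paste0("S:", idx))
  dimnames(E) <- list(ids, paste0("E:", idx))
  structure(
    list(ids = ids, steric = S, electrostatic = E, grid = grid,
         probe = probe, cutoff = cutoff,
         kept = rep(TRUE, 2L * length(idx)), threshold = 0),
    class = "field_matrix"
  )
}

#' Combined descriptor matrix of a field matrix
#' @param fm a `field_matrix`.
#' @param filtered return only the columns kept by [column_filter()].
#' @return numeric matrix, molecules x grid-columns.
#' @export
field_values <- function(fm, filtered = TRUE) {
  x <- cbind(fm$steric, fm$electrostatic)
  if (filtered) x[, fm$kept, drop = FALSE] else x
}

#' @export
print.field_matrix <- function(x, ...) {
  cat(sprintf("<field_matrix: %d molecules x (2 x %d) grid columns, %d kept>\n",
    length(x$ids), ncol(x$steric), sum(x$kept)))
  invisible(x)
}

#' Drop low-variance field columns
#'
#' Standard CoMFA column filtering: columns whose energy standard deviation
#' falls below `threshold` (kcal/mol) are excluded from the PLS analysis.
#'
#' @param fm a `field_matrix`.
#' @param threshold minimum column standard deviation (default 2.0).
#' @return the `field_matrix` with its `kept` mask set.
#' @export
column_filter <- function(fm, threshold = 2.0) {
  stopifnot(threshold >= 0)
  x <- field_values(fm, filtered = FALSE)
  sds <- apply(x, 2, stats::sd)
  kept <- if (threshold == 0) rep(TRUE, ncol(x)) else sds >= threshold
  if (!any(kept)) stop("no variance above threshold: all columns dropped")
  fm$kept <- unname(kept)
  fm$threshold <- threshold
  fm
}
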