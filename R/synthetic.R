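# Synthetic data with planted structure: low-rank descriptor matrices with a
# known linear activity relationship, and toy scaffold+substituent compound
# libraries whose activity is driven by planted steric/electrostatic rules.
# Both exist so the field/PLS/contour machinery can be verified end-to-end
# against ground truth.

#' Specification of a planted low-rank field matrix
#'
#' @param n_molecules number of rows (default 20, matching the size of a
#'   typical CoMFA training set).
#' @param n_steric_cols,n_electro_cols columns per field block.
#' @param n_latent number of latent factors generating X.
#' @param b named or plain coefficient vector of length
#'   `n_steric_cols + n_electro_cols`, or `NULL` to draw a sparse one.
#' @param noise_sd Gaussian noise on the response, pIC50 units.
#' @param seed integer seed.
#' @return a `planted_spec` list.
#' @export
planted_spec <- function(n_molecules = 20L, n_steric_cols = 100L,
                         n_electro_cols = 100L, n_latent = 2L,
                         b = NULL, noise_sd = 0.1, seed = 1L) {
  stopifnot(n_latent <= n_molecules - 2L, noise_sd >= 0)
  structure(list(
    n_molecules = n_molecules, n_steric_cols = n_steric_cols,
    n_electro_cols = n_electro_cols, n_latent = n_latent, b = b,
    noise_sd = noise_sd, seed = seed
  ), class = "planted_spec")
}

#' Generate a planted low-rank matrix with linear activity
#'
#' X = T P' + E with `n_latent` factors (small isotropic residual E), and
#' y = X b_true + noise. This is exactly the model class PLS assumes, so a
#' correct pipeline must recover b_true's direction as noise vanishes.
#'
#' @param spec a [planted_spec()].
#' @return list(X, y, b_true); X carries `S:`/`E:` column names.
#' @export
generate_planted_matrix <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  p <- spec$n_steric_cols + spec$n_electro_cols
  if (p < 1L || spec$n_molecules < 3L) stop("degenerate dimensions")
  .with_seed(spec$seed, {
    Tm <- matrix(stats::rnorm(spec$n_molecules * spec$n_latent),
                 spec$n_molecules, spec$n_latent)
    P <- matrix(stats::rnorm(p * spec$n_latent), p, spec$n_latent)
    X <- Tm %*% t(P) + 0.01 * matrix(stats::rnorm(spec$n_molecules * p),
                                     spec$n_molecules, p)
    b_true <- spec$b
    if (is.null(b_true)) {
      # plant the coefficients inside the latent span of X, so that the
      # direction is identifiable from (X, y) and recovery is a sharp test
      b_true <- as.vector(P %*% stats::rnorm(spec$n_latent))
      b_true <- b_true / sqrt(sum(b_true^2))
    }
    y <- as.vector(X %*% b_true) + stats::rnorm(spec$n_molecules, 0, spec$noise_sd)
    colnames(X) <- c(paste0("S:", seq_len(spec$n_steric_cols) - 1L),
                     paste0("E:", seq_len(spec$n_electro_cols) - 1L))
    list(X = X, y = y, b_true = b_true)
  })
}

#' Specification of a toy scaffold+substituent library
#'
#' Molecules are enumerated from a purine scaffold with a substituent at the
#' C-2 site (site A, steric driver) and an aryl group at C-6 whose para
#' substituent is either electron-withdrawing or not (site B, electrostatic
#' driver). Planted activity (pIC50):
#' `base + w_s * heavy_atoms(site A) + w_e * is_EWG(site B) + noise`.
#'
#' @param w_s weight per heavy atom of the site-A substituent.
#' @param w_e weight of an electron-withdrawing para group at site B.
#' @param n_molecules how many scaffold decorations to enumerate (max 36).
#' @param base baseline pIC50.
#' @param noise_sd Gaussian noise, pIC50 units.
#' @param seed integer seed.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(w_s = -0.15, w_e = 0.8, n_molecules = 12L,
                     base = 6.0, noise_sd = 0.05, seed = 1L) {
  structure(list(w_s = w_s, w_e = w_e, n_molecules = n_molecules,
                 base = base, noise_sd = noise_sd, seed = seed),
            class = "toy_spec")
}

# site-A pool: substituents of increasing bulk at C-2
.toy_site_a <- c(H = "", methyl = "C", ethyl = "CC", isopropyl = "C(C)C",
                 cyclopentyl = "C1CCCC1", cyclohexyl = "C1CCCCC1")
# site-B pool: para substituent on the 6-phenyl ring; EWG flag
.toy_site_b <- data.frame(
  name = c("H", "methyl", "methoxy", "nitro", "trifluoromethyl", "chloro"),
  frag = c("", "C", "OC", "[N+](=O)[O-]", "C(F)(F)F", "Cl"),
  ewg = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Generate a toy compound library with planted activity
#'
#' @param spec a [toy_spec()].
#' @return list(compounds, activities, truth): compound records
#'   (id/smiles/series/formula/name), an activity table on the synthetic
#'   cell line `"SYN"` stored as IC50 micromolar, and the per-compound
#'   planted drivers.
#' @export
generate_toy_library <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  combos <- expand.grid(a = seq_along(.toy_site_a),
                        b = seq_len(nrow(.toy_site_b)))
  if (spec$n_molecules > nrow(combos)) stop("at most ", nrow(combos), " molecules")
  .with_seed(spec$seed, {
    pick <- combos[sample(nrow(combos), spec$n_molecules), ]
    rows <- lapply(seq_len(nrow(pick)), function(k) {
      afrag <- .toy_site_a[[pick$a[k]]]
      brow <- .toy_site_b[pick$b[k], ]
      r2 <- if (nzchar(afrag)) afrag else "[H]"
      aryl <- if (nzchar(brow$frag)) {
        paste0("c1ccc(", brow$frag, ")cc1")
      } else "c1ccccc1"
      smiles <- paste0("Cn1cnc2c1nc(", r2, ")nc2-", aryl)
      n_heavy_a <- sum(strsplit(gsub("[^A-Z]", "", afrag), "")[[1]] %in%
                         c("C", "N", "O", "F", "S"))
      id <- sprintf("syn%02d", k)
      data.frame(id = id, smiles = smiles, series = "I",
                 formula = format_formula(smiles_formula(smiles)),
                 name = paste0("toy ", names(.toy_site_a)[pick$a[k]], "/",
                               brow$name),
                 heavy_a = n_heavy_a, ewg_b = brow$ewg,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, rows)
    pic50 <- spec$base + spec$w_s * d$heavy_a + spec$w_e * d$ewg_b +
      stats::rnorm(nrow(d), 0, spec$noise_sd)
    activities <- data.frame(
      compound_id = d$id, cell_line = "SYN",
      ic50_um = 10^(6 - pic50), censored = FALSE
    )
    list(
      compounds = d[, c("id", "smiles", "series", "formula", "name")],
      activities = activities,
      truth = data.frame(id = d$id, heavy_a = d$heavy_a, ewg_b = d$ewg_b,
                         pic50 = pic50)
    )
  })
}
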