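# End-to-end orchestration: structures -> alignment -> fields -> PLS ->
# contours -> report, driven by a single configuration list whose defaults
# are the classic CoMFA settings (2 A grid, sp3 C+ probe, 30 kcal/mol
# cutoff, 2.0 column filter).

#' Pipeline configuration
#'
#' All tunables of the reproduction pipeline in one list. Defaults follow
#' the standard CoMFA protocol: grid spacing 2.0 A, probe vdW radius 1.52 A
#' and charge +1.0 e, field cutoff 30.0 kcal/mol, column filter 2.0
#' kcal/mol, 75% training split.
#'
#' @param compounds,activities paths to the library / activity CSVs
#'   (defaults: the packaged purine data).
#' @param cell_line cell line to model.
#' @param spacing,margin grid spacing / clearance, Angstrom.
#' @param probe a [probe_spec()].
#' @param cutoff field truncation, kcal/mol.
#' @param filter_threshold column filter, kcal/mol.
#' @param train_fraction,seed split fraction and seed (seed also fixes the
#'   conformer builder input order).
#' @param train,test optional explicit split id lists.
#' @param n_max component search upper bound (further capped at floor(n/3)).
#' @param upper_pct,lower_pct contour percentile levels.
#' @param reference reference compound id for contour annotation (default
#'   `"7h"`, the most potent compound; falls back to the template).
#' @param q2_mean q2 denominator convention, `"full"` or `"fold"`.
#' @return a `comfa_config` list.
#' @export
comfa_config <- function(compounds = comfa_file("compounds.csv"),
                         activities = comfa_file("activities_reconstructed.csv"),
                         cell_line = "HL-60",
                         spacing = 2.0, margin = 4.0,
                         probe = probe_spec(),
                         cutoff = 30.0, filter_threshold = 2.0,
                         train_fraction = 0.75, seed = 20191225L,
                         train = NULL, test = NULL,
                         n_max = 10L, upper_pct = 80, lower_pct = 20,
                         reference = "7h", q2_mean = "full") {
  structure(as.list(environment()), class = "comfa_config")
}

#' Run the full CoMFA pipeline
#'
#' Loads the compound library and activity table, prepares one aligned,
#' charged conformer per modelled compound, computes and filters the field
#' matrix, splits into training and test sets, selects the number of PLS
#' components by LOO q2 on the training set, fits the final model, computes
#' the model statistics (q2, r2, SEE, r2pred, field contributions), and
#' extracts and locates the steric and electrostatic contour regions.
#'
#' @param config a [comfa_config()].
#' @param molecules optional pre-built aligned molecules (a list of
#'   `molecule`), to reuse conformers across runs.
#' @return a `comfa_run` list: config echo, dataset, split, stats, model,
#'   field matrix, contours, per-compound predictions, and
#'   `contour_checks` (qualitative region/position relations).
#' @export
run_pipeline <- function(config = comfa_config(), molecules = NULL) {
  lib <- load_library(config$compounds)
  act <- if (is.data.frame(config$activities)) config$activities else
    load_activities(config$activities)
  ds <- qsar_compounds(lib, act, config$cell_line)
  if (nrow(ds) < 5) stop("fewer than 5 modelled compounds")

  if (is.null(molecules)) {
    molecules <- prepare_molecules(ds, seed = config$seed)
  }
  aligned <- align_to_scaffold(molecules[ds$id])
  grid <- build_grid(aligned, spacing = config$spacing, margin = config$margin)
  fm <- compute_field_matrix(aligned, grid, probe = config$probe,
                             cutoff = config$cutoff)
  fm <- column_filter(fm, config$filter_threshold)
  X <- field_values(fm)
  y <- stats::setNames(ds$pic50, ds$id)

  split <- split_train_test(ds$id, fraction = config$train_fraction,
                            seed = config$seed,
                            train = config$train, test = config$test)
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- y[split$train]
  Xte <- X[split$test, , drop = FALSE]
  yte <- y[split$test]

  sel <- select_components(Xtr, ytr, n_max = config$n_max,
                           mean = config$q2_mean)
  model <- fit_pls(Xtr, ytr, sel$ncomp)
  stats <- final_stats(model, Xtr, ytr, Xte, yte, q2 = sel$q2,
                       mean = config$q2_mean)

  # contour maps are displayed from the training-set model
  fm_train <- fm
  fm_train$steric <- fm$steric[split$train, , drop = FALSE]
  fm_train$electrostatic <- fm$electrostatic[split$train, , drop = FALSE]
  vals <- stdev_coeff_values(model, fm_train)
  ref <- if (config$reference %in% ds$id) config$reference else aligned$template_id
  cs_st <- extract_contours(vals$steric, config$upper_pct, config$lower_pct,
                            kind = "steric")
  cs_el <- extract_contours(vals$electrostatic, config$upper_pct,
                            config$lower_pct, kind = "electrostatic")
  reg_st <- locate_contours(cs_st, aligned, grid, reference = ref)
  reg_el <- locate_contours(cs_el, aligned, grid, reference = ref)

  loo <- loo_q2(Xtr, ytr, sel$ncomp, mean = config$q2_mean)
  predictions <- data.frame(
    id = c(split$train, split$test),
    set = rep(c("train", "test"), c(length(split$train), length(split$test))),
    y_obs = c(ytr, yte),
    y_fit = c(predict(model, Xtr), predict(model, Xte)),
    y_loo = c(loo$predictions, rep(NA_real_, length(split$test)))
  )

  # qualitative contour check: is some steric-disfavoured region closer to
  # the C-2 substituent than to the N-9 substituent of the reference?
  dis <- reg_st[reg_st$polarity == "disfavoured", , drop = FALSE]
  checks <- list(
    steric_disfavoured_near_C2 =
      nrow(dis) > 0 && any(dis$dist_C2 < dis$dist_N9)
  )

  structure(list(
    config = config, dataset = ds, split = split, ncomp_search = sel,
    model = model, stats = stats, field_matrix = fm, grid = grid,
    aligned = aligned, contours = list(steric = cs_st, electrostatic = cs_el),
    regions = list(steric = reg_st, electrostatic = reg_el),
    predictions = predictions, contour_checks = checks
  ), class = "comfa_run")
}

#' @export
print.comfa_run <- function(x, ...) {
  cat(sprintf("CoMFA run: %s, %d compounds (train %d / test %d)\n",
    x$config$cell_line, nrow(x$dataset),
    length(x$split$train), length(x$split$test)))
  print(x$stats)
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the config echo, split membership, model statistics, contour
#' region summaries and per-compound predictions as JSON.
#'
#' @param run a `comfa_run`.
#' @param path output file.
#' @export
write_run_report <- function(run, path) {
  cfg <- run$config
  cfg$probe <- unclass(cfg$probe)
  report <- list(
    config = cfg[!vapply(cfg, is.null, TRUE)],
    n_modelled = nrow(run$dataset),
    split = run$split,
    stats = unclass(run$stats),
    regions = run$regions,
    contour_checks = run$contour_checks,
    predictions = run$predictions
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
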