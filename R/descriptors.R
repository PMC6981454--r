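# Molecular property profiling: selectivity indices, Lipinski rule-of-five
# compliance, and exact masses (see formula.R for the mass utilities).

#' Selectivity index
#'
#' SI = IC50 on the non-neoplastic reference line (MRC-5) divided by IC50 on
#' the tumour line; higher means more tumour-selective. A censored reference
#' IC50 (">X") propagates to a lower bound, flagged in the result.
#'
#' @param ic50_reference IC50 (micromolar) on the reference (MRC-5) line.
#' @param ic50_line IC50 (micromolar) on the tumour line (must not be
#'   censored).
#' @param reference_censored is the reference value a ">X" bound?
#' @param line_censored is the tumour-line value censored? (error if TRUE).
#' @return list(si, lower_bound): the SI value and whether it is only a
#'   lower bound ("greater than or equal").
#' @examples
#' selectivity_index(100, 0.4) # SI = 250
#' @export
selectivity_index <- function(ic50_reference, ic50_line,
                              reference_censored = FALSE,
                              line_censored = FALSE) {
  if (isTRUE(line_censored)) stop("censored tumour-line IC50: SI undefined")
  stopifnot(ic50_reference > 0, ic50_line > 0)
  list(si = ic50_reference / ic50_line, lower_bound = isTRUE(reference_censored))
}

#' Selectivity indices for a whole activity table
#'
#' @param activities activity table ([load_activities()]).
#' @param cell_line tumour cell line to compare against MRC-5.
#' @return data.frame(compound_id, si, lower_bound); compounds censored on
#'   the tumour line are omitted.
#' @export
selectivity_table <- function(activities, cell_line) {
  ref <- activities[activities$cell_line == "MRC-5", ]
  tum <- activities[activities$cell_line == cell_line & !activities$censored, ]
  d <- merge(tum, ref, by = "compound_id", suffixes = c("", ".ref"))
  data.frame(
    compound_id = d$compound_id,
    si = d$ic50_um.ref / d$ic50_um,
    lower_bound = d$censored.ref
  )
}

# Lipinski hydrogen-bond donors/acceptors by the original N/O counting:
# donors = N-H and O-H hydrogens, acceptors = all N and O atoms.
.count_hbd_hba <- function(mol) {
  el <- mol$atoms$element
  no <- which(el %in% c("N", "O"))
  hbd <- 0L
  for (k in seq_len(nrow(mol$bonds))) {
    f <- mol$bonds$from[k]; t <- mol$bonds$to[k]
    if ((el[f] == "H" && t %in% no) || (el[t] == "H" && f %in% no)) {
      hbd <- hbd + 1L
    }
  }
  c(hbd = hbd, hba = length(no))
}

#' Lipinski rule-of-five profile
#'
#' Molecular weight (average masses), atom-contribution logP (Open Babel),
#' hydrogen-bond donors (O-H/N-H) and acceptors (N+O count), monoisotopic
#' \[M+H\]+, and the count of rule-of-five violations
#' (MW > 500, logP > 5, HBD > 5, HBA > 10).
#'
#' @param mol a `molecule`, or a SMILES string.
#' @param smiles the molecule's SMILES (needed for logP when `mol` is a
#'   `molecule`; taken from `mol` when it carries a `smiles` attribute).
#' @return a `property_profile` list: molecular_weight, clogp, hbd, hba,
#'   monoisotopic_mh, lipinski_violations.
#' @export
lipinski_profile <- function(mol, smiles = NULL) {
  if (is.character(mol)) {
    smiles <- mol
    mol <- embed_conformer(list(id = smiles, smiles = smiles))
  }
  if (is.null(smiles)) smiles <- attr(mol, "smiles")
  counts <- table(mol$atoms$element)
  counts <- stats::setNames(as.integer(counts), names(counts))
  mw <- molecular_weight(counts)
  clogp <- if (!is.null(smiles)) smiles_logp(smiles) else NA_real_
  hb <- .count_hbd_hba(mol)
  violations <- sum(mw > 500, isTRUE(clogp > 5), hb[["hbd"]] > 5, hb[["hba"]] > 10)
  structure(list(
    molecular_weight = mw, clogp = clogp,
    hbd = hb[["hbd"]], hba = hb[["hba"]],
    monoisotopic_mh = monoisotopic_mh(counts),
    lipinski_violations = violations
  ), class = "property_profile")
}

#' @export
print.property_profile <- function(x, ...) {
  cat(sprintf(
    "MW %.1f  logP %.2f  HBD %d  HBA %d  [M+H]+ %.4f  violations %d\n",
    x$molecular_weight, x$clogp, x$hbd, x$hba, x$monoisotopic_mh,
    x$lipinski_violations))
  invisible(x)
}

#' Property table for a compound library
#' @param records compound records ([load_library()]).
#' @return data.frame, one row per compound, with the
#'   [lipinski_profile()] fields.
#' @export
property_table <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    p <- lipinski_profile(embed_conformer(as.list(records[i, ])),
                          smiles = records$smiles[i])
    data.frame(id = records$id[i], mw = p$molecular_weight, clogp = p$clogp,
               hbd = p$hbd, hba = p$hba, mh = p$monoisotopic_mh,
               violations = p$lipinski_violations)
  })
  do.call(rbind, rows)
}
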