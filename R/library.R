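# Compound-library and activity-table readers. The packaged defaults carry
# the 31 final trisubstituted purines (series I-III), the synthesis
# intermediates, and the reconstructed cytotoxicity table (IC50, micromolar,
# eight cell lines, censoring-aware).

.cell_lines <- c("CFPAC-1", "NCI-H460", "HL-60", "CACO2",
                 "HCT-116", "K562", "MCF-7", "MRC-5")

#' Cell lines of the cytotoxicity panel
#' @return character vector of the eight panel cell lines (seven tumour
#'   lines plus the MRC-5 non-neoplastic fibroblast control).
#' @export
cell_lines <- function() .cell_lines

#' Path to a packaged data file
#' @param file file name under the package's `extdata`.
#' @return absolute path.
#' @export
comfa_file <- function(file) {
  p <- system.file("extdata", file, package = "comfa")
  if (!nzchar(p)) stop("packaged file not found: ", file)
  p
}

#' Load a compound library
#'
#' Reads a CSV with columns `id, smiles, series, formula, name` and
#' validates each record: the SMILES must parse, ids must be unique, and
#' `series` must be one of I, II, III or `intermediate`. With
#' `check_formula = TRUE` the element counts recomputed from the SMILES
#' (implicit hydrogens included) must equal the stored formula.
#'
#' @param source path to the CSV; defaults to the packaged purine library.
#' @param check_formula validate stored formulas against the SMILES
#'   (one Open Babel call per record).
#' @return data.frame of validated compound records.
#' @export
load_library <- function(source = comfa_file("compounds.csv"),
                         check_formula = FALSE) {
  if (!file.exists(source)) stop("no such file: ", source)
  d <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "series", "formula", "name")
  if (!all(need %in% names(d))) {
    stop("library file must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(d) == 0L) stop("no records")
  if (anyDuplicated(d$id)) {
    stop("duplicate id(s): ", paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  }
  bad <- !d$series %in% c("I", "II", "III", "intermediate")
  if (any(bad)) stop("invalid series for: ", paste(d$id[bad], collapse = ", "))
  for (i in seq_len(nrow(d))) {
    counts <- tryCatch(smiles_formula(d$smiles[i]), error = function(e) {
      stop("record '", d$id[i], "': unparsable SMILES (", conditionMessage(e), ")")
    })
    if (check_formula) {
      stored <- parse_formula(d$formula[i])
      if (!identical(counts[order(names(counts))], stored[order(names(stored))])) {
        stop("record '", d$id[i], "': SMILES formula ", format_formula(counts),
             " != stored ", d$formula[i])
      }
    }
  }
  d
}

#' Write a compound library back to CSV
#' @param records data.frame as returned by [load_library()].
#' @param path output CSV path.
#' @export
write_library <- function(records, path) {
  utils::write.csv(records[, c("id", "smiles", "series", "formula", "name")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Load a cytotoxicity activity table
#'
#' Reads a CSV with columns `compound_id, cell_line, ic50_um, censored`.
#' Censored entries (printed ">X" in assay tables) keep the bound X with
#' `censored = TRUE`; they are never converted to pIC50 and never enter a
#' regression design matrix.
#'
#' @param source path to the CSV; defaults to the packaged (partly
#'   reconstructed) purine cytotoxicity table.
#' @param provenance tag recorded on the result (`"packaged"` or `"user"`).
#' @return data.frame with attribute `provenance`.
#' @export
load_activities <- function(source = comfa_file("activities_reconstructed.csv"),
                            provenance = if (missing(source)) "packaged" else "user") {
  if (!file.exists(source)) stop("no such file: ", source)
  d <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("compound_id", "cell_line", "ic50_um", "censored")
  if (!all(need %in% names(d))) {
    stop("activity file must have columns: ", paste(need, collapse = ", "))
  }
  d$censored <- as.logical(d$censored)
  if (any(!is.finite(d$ic50_um) | d$ic50_um <= 0)) {
    stop("nonpositive IC50 for: ",
      paste(d$compound_id[!is.finite(d$ic50_um) | d$ic50_um <= 0], collapse = ", "))
  }
  bad <- !d$cell_line %in% .cell_lines
  if (any(bad)) stop("unknown cell line(s): ",
    paste(unique(d$cell_line[bad]), collapse = ", "))
  if (anyDuplicated(d[, c("compound_id", "cell_line")])) {
    stop("more than one measurement per (compound, cell line)")
  }
  attr(d, "provenance") <- provenance
  d
}

#' Assemble a QSAR dataset for one cell line
#'
#' Joins the compound library with the activity table for one cell line,
#' drops intermediates and censored measurements (which have no pIC50), and
#' returns ids with their pIC50 response.
#'
#' @param library compound records ([load_library()]).
#' @param activities activity table ([load_activities()]).
#' @param cell_line one of [cell_lines()].
#' @return data.frame(id, smiles, ic50_um, pic50).
#' @export
qsar_compounds <- function(library, activities, cell_line) {
  if (!cell_line %in% activities$cell_line) {
    stop("no measurements for cell line '", cell_line, "'")
  }
  lib <- library[library$series != "intermediate", ]
  act <- activities[activities$cell_line == cell_line & !activities$censored, ]
  act <- act[act$compound_id %in% lib$id, ]
  d <- merge(lib[, c("id", "smiles")], act,
             by.x = "id", by.y = "compound_id", sort = TRUE)
  d$pic50 <- ic50_to_pic50(d$ic50_um)
  d[, c("id", "smiles", "ic50_um", "pic50")]
}
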