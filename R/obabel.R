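# Thin wrappers around the Open Babel command-line tool. Structure
# generation, Gasteiger charges and logP are delegated to obabel; everything
# numerical downstream is computed in the package.

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("Open Babel ('obabel') not found on PATH")
  p
}

.run_obabel <- function(args, input = NULL) {
  out <- suppressWarnings(system2(.obabel_path(), shQuote(args),
    stdout = TRUE, stderr = FALSE, input = input
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("obabel failed (exit ", status, "): obabel ", paste(args, collapse = " "))
  }
  out
}

#' Molecular formula of a SMILES string (via Open Babel)
#' @param smiles SMILES string.
#' @return Named integer vector of element counts (implicit hydrogens
#'   included).
#' @export
smiles_formula <- function(smiles) {
  out <- .run_obabel(c(paste0("-:", smiles), "-osmi", "--append", "formula"))
  if (!length(out)) stop("obabel could not parse SMILES: ", smiles)
  f <- tail(strsplit(out[[1]], "\t")[[1]], 1L)
  # strip charge suffixes like "+" that obabel appends for ions
  parse_formula(gsub("[+-]+$", "", trimws(f)))
}

#' Atom-contribution logP of a SMILES string (via Open Babel)
#' @param smiles SMILES string.
#' @return Numeric logP estimate.
#' @export
smiles_logp <- function(smiles) {
  out <- .run_obabel(c(paste0("-:", smiles), "-osmi", "--append", "logP"))
  as.numeric(tail(strsplit(out[[1]], "\t")[[1]], 1L))
}

# Parse Tripos MOL2 text into atom/bond tables.
.parse_mol2 <- function(lines) {
  sec <- function(name) {
    i <- which(lines == paste0("@<TRIPOS>", name))
    if (!length(i)) return(character(0))
    j <- grep("^@<TRIPOS>", lines)
    j <- j[j > i[1]]
    end <- if (length(j)) j[1] - 1L else length(lines)
    lines[(i[1] + 1L):end]
  }
  at <- sec("ATOM")
  at <- at[nzchar(trimws(at))]
  if (!length(at)) stop("mol2 output contains no atoms")
  f <- strsplit(trimws(at), "[[:space:]]+")
  atoms <- data.frame(
    element = vapply(f, function(x) sub("\\..*$", "", x[6]), ""),
    x = vapply(f, function(x) as.numeric(x[3]), 0),
    y = vapply(f, function(x) as.numeric(x[4]), 0),
    z = vapply(f, function(x) as.numeric(x[5]), 0),
    charge = vapply(f, function(x) if (length(x) >= 9) as.numeric(x[9]) else 0, 0),
    stringsAsFactors = FALSE
  )
  bd <- sec("BOND")
  bd <- bd[nzchar(trimws(bd))]
  fb <- strsplit(trimws(bd), "[[:space:]]+")
  bonds <- data.frame(
    from = vapply(fb, function(x) as.integer(x[2]), 0L),
    to = vapply(fb, function(x) as.integer(x[3]), 0L),
    order = vapply(fb, function(x) x[4], ""),
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, bonds = bonds)
}

# Write a V2000 SDF block for a molecule (used to round-trip through obabel).
.write_sdf <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  ord <- vapply(b$order, function(o) switch(o, ar = 4L, am = 1L, as.integer(o)), 0L)
  header <- c(mol$id, " comfa", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  atoms <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    a$x, a$y, a$z, a$element
  )
  bonds <- sprintf("%3d%3d%3d  0  0  0  0", b$from, b$to, ord)
  chg <- character(0)
  fc <- if (is.null(a$fcharge)) integer(nrow(a)) else a$fcharge
  hot <- which(fc != 0)
  if (length(hot)) {
    chg <- paste0("M  CHG", sprintf("%3d", length(hot)),
                  paste0(sprintf("%4d%4d", hot, fc[hot]), collapse = ""))
  }
  c(header, counts, atoms, bonds, chg, "M  END", "$$$$")
}
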