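# Molecule container and conformer preparation.
#
# A `molecule` is a list with:
#   id         compound label
#   atoms      data.frame(element, x, y, z, charge, vdw, heavy)
#   bonds      data.frame(from, to, order)  (order: "1","2","3","ar","am")
#   net_charge integer total formal charge

# Bondi van der Waals radii (Angstrom).
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Cl = 1.75, S = 1.80, P = 1.80, Br = 1.85, I = 1.98
)

.new_molecule <- function(id, atoms, bonds, net_charge = 0L) {
  miss <- setdiff(unique(atoms$element), names(.vdw_radii))
  if (length(miss)) stop("no van der Waals radius for element(s): ",
    paste(miss, collapse = ", "))
  if (is.null(atoms$fcharge)) atoms$fcharge <- 0L
  atoms$vdw <- unname(.vdw_radii[atoms$element])
  atoms$heavy <- atoms$element != "H"
  structure(
    list(id = id, atoms = atoms, bonds = bonds, net_charge = net_charge),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule %s: %d atoms (%d heavy), %d bonds, net charge %+d>\n",
    x$id, nrow(x$atoms), sum(x$atoms$heavy), nrow(x$bonds), x$net_charge
  ))
  invisible(x)
}

#' Coordinates of a molecule as a matrix
#' @param mol a `molecule`.
#' @param heavy_only restrict to non-hydrogen atoms.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(mol, heavy_only = FALSE) {
  a <- mol$atoms
  if (heavy_only) a <- a[a$heavy, ]
  as.matrix(a[, c("x", "y", "z")])
}

#' Generate a single reproducible 3D conformer
#'
#' Builds one 3D conformer by seeded ETKDG distance-geometry embedding
#' followed by MMFF94 force-field minimization (RDKit, invoked through the
#' system Python). The fixed seed makes the construction fully
#' deterministic: the same (record, seed) pair always yields
#' bitwise-identical coordinates.
#'
#' Partial charges are left at zero; use [assign_charges()].
#'
#' @param record a list/row with `id` and `smiles` fields (a
#'   `CompoundRecord`), or a SMILES string.
#' @param seed integer seed for the distance-geometry embedding
#'   (default 20191225).
#' @return a `molecule` with 3D coordinates in Angstrom.
#' @export
embed_conformer <- function(record, seed = 20191225L) {
  if (is.character(record)) record <- list(id = record, smiles = record)
  stopifnot(!is.null(record$smiles))
  parsed <- tryCatch(.rdkit_embed(record$smiles, seed), error = function(e) {
    stop("3D embedding failed for '", record$id, "': ", conditionMessage(e))
  })
  .new_molecule(record$id, parsed$atoms, parsed$bonds,
                net_charge = sum(parsed$atoms$fcharge))
}

#' Assign Gasteiger partial charges
#'
#' Computes Gasteiger partial charges (iterative partial equalization of
#' orbital electronegativity) for an embedded molecule through Open Babel,
#' keeping the molecule's coordinates untouched. Charges sum to the net
#' formal charge; topologically equivalent atoms receive equal charges.
#'
#' @param mol a `molecule` with explicit hydrogens.
#' @return the molecule with `atoms$charge` filled and `net_charge` set.
#' @export
assign_charges <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  sdf <- .write_sdf(mol)
  out <- .run_obabel(
    c("-isdf", "-omol2", "--partialcharge", "gasteiger"),
    input = sdf
  )
  parsed <- .parse_mol2(out)
  if (nrow(parsed$atoms) != nrow(mol$atoms)) {
    stop("charge assignment changed the atom count for '", mol$id, "'")
  }
  if (any(!is.finite(parsed$atoms$charge))) {
    stop("Gasteiger charges undefined for some atoms of '", mol$id, "'")
  }
  mol$atoms$charge <- parsed$atoms$charge
  mol$net_charge <- as.integer(round(sum(parsed$atoms$charge)))
  mol
}

#' Prepare conformers for a set of compound records
#'
#' Convenience wrapper: [embed_conformer()] + [assign_charges()] for each
#' row of a compound table.
#'
#' @param records data.frame with `id` and `smiles` columns.
#' @param seed integer seed passed to [embed_conformer()].
#' @return list of `molecule` objects, named by id.
#' @export
prepare_molecules <- function(records, seed = 20191225L) {
  mols <- lapply(seq_len(nrow(records)), function(i) {
    assign_charges(embed_conformer(as.list(records[i, ]), seed = seed))
  })
  names(mols) <- records$id
  mols
}

# Apply a rigid transform x -> x R + t to all atoms.
.transform_molecule <- function(mol, rot, trans) {
  xyz <- coords(mol) %*% rot
  mol$atoms$x <- xyz[, 1] + trans[1]
  mol$atoms$y <- xyz[, 2] + trans[2]
  mol$atoms$z <- xyz[, 3] + trans[3]
  mol
}
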