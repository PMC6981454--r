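# Shared, lazily-built fixtures. Conformer generation and full pipeline runs
# are the slow parts, so they are computed once per test session and reused.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

fx_library <- function() memo("library", load_library())
fx_activities <- function() memo("activities", load_activities())

fx_molecule <- function(smiles, id = smiles) {
  memo(paste0("mol:", smiles),
       assign_charges(embed_conformer(list(id = id, smiles = smiles))))
}

# one pipeline run per cell line, shared between pipeline and acceptance tests
fx_run <- function(cell_line) {
  memo(paste0("run:", cell_line),
       run_pipeline(comfa_config(cell_line = cell_line)))
}

# small hand-built molecule: n atoms at given coordinates, no obabel involved
fake_molecule <- function(id, element, xyz, charge = 0, bonds = NULL) {
  atoms <- data.frame(
    element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, length(element)),
    stringsAsFactors = FALSE
  )
  if (is.null(bonds)) bonds <- data.frame(from = integer(0), to = integer(0),
                                          order = character(0))
  comfa:::.new_molecule(id, atoms, bonds)
}

fake_aligned <- function(mols) {
  ids <- vapply(mols, `[[`, "", "id")
  names(mols) <- ids
  structure(list(molecules = mols, mappings = NULL, rmsd = rep(0, length(mols)),
                 scaffold = NULL, template_id = ids[[1]]),
            class = "aligned_set")
}

rigid_transform <- function(mol, angle = 0.7, axis = c(0, 0, 1),
                            shift = c(3, -2, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) * c + s * K + (1 - c) * tcrossprod(axis)
  comfa:::.transform_molecule(mol, R, shift)
}
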