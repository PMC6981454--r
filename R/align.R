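# Rigid scaffold alignment: maximum-common-scaffold superposition of every
# molecule onto the first one, using least-squares (Kabsch) fitting of the
# atoms matched to a shared substructure.

#' The 9H-purine core scaffold
#'
#' Returns the bicyclic purine core (9 heavy atoms) used as the default
#' alignment template for 2,6,9-trisubstituted purines, with ring positions
#' named by the standard purine numbering (N1, C2, N3, C4, C5, C6, N7, C8,
#' N9).
#'
#' @return A `scaffold` object: list with `atoms` (element vector named by
#'   position) and `bonds` (data.frame from/to, position names).
#' @export
purine_scaffold <- function() {
  atoms <- c(
    N1 = "N", C2 = "C", N3 = "N", C4 = "C", C5 = "C",
    C6 = "C", N7 = "N", C8 = "C", N9 = "N"
  )
  bonds <- data.frame(
    from = c("N1", "C2", "N3", "C4", "C5", "C6", "C4", "N9", "C8", "N7"),
    to   = c("C2", "N3", "C4", "C5", "C6", "N1", "N9", "C8", "N7", "C5"),
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, bonds = bonds), class = "scaffold")
}

# igraph of a molecule's heavy atoms, with element stored as vertex colour.
.heavy_graph <- function(mol) {
  heavy <- which(mol$atoms$heavy)
  remap <- match(seq_len(nrow(mol$atoms)), heavy)
  b <- mol$bonds
  keep <- !is.na(remap[b$from]) & !is.na(remap[b$to])
  g <- igraph::graph_from_data_frame(
    data.frame(from = remap[b$from[keep]], to = remap[b$to[keep]]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(heavy))
  )
  list(graph = g, orig_index = heavy, element = mol$atoms$element[heavy])
}

.scaffold_graph <- function(scaffold) {
  pos <- names(scaffold$atoms)
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(scaffold$bonds$from, pos),
               to = match(scaffold$bonds$to, pos)),
    directed = FALSE, vertices = data.frame(name = seq_along(pos))
  )
  list(graph = g, element = unname(scaffold$atoms), positions = pos)
}

# All mappings of scaffold positions onto heavy-atom indices of mol.
.scaffold_matches <- function(mol, scaffold) {
  sg <- .scaffold_graph(scaffold)
  hg <- .heavy_graph(mol)
  els <- sort(unique(c(sg$element, hg$element)))
  # for vf2, vertex.color1 belongs to the target graph, color2 to the pattern
  maps <- igraph::subgraph_isomorphisms(
    sg$graph, hg$graph, method = "vf2",
    vertex.color1 = match(hg$element, els),
    vertex.color2 = match(sg$element, els)
  )
  lapply(maps, function(m) {
    idx <- hg$orig_index[as.integer(m)]
    names(idx) <- sg$positions
    idx
  })
}

# Kabsch: optimal rotation/translation mapping x onto y (n x 3 each).
.kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  s <- svd(crossprod(sweep(x, 2, cx), sweep(y, 2, cy)))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rot = rot, trans = cy - as.vector(cx %*% rot))
}

.rmsd <- function(x, y) sqrt(mean(rowSums((x - y)^2)))

#' Align molecules onto a common scaffold
#'
#' Superimposes each molecule's scaffold atoms onto those of the template
#' (the first molecule) by rigid-body least squares. Substructure matching
#' is done on the heavy-atom graph with element labels; when a scaffold
#' matches a molecule in more than one way, the mapping giving the smallest
#' scaffold RMSD is kept.
#'
#' @param mols list of `molecule` objects (first = template).
#' @param scaffold a `scaffold` object (default [purine_scaffold()]) or a
#'   SMILES string defining the common substructure.
#' @return An `aligned_set`: list with `molecules` (transformed), `mappings`
#'   (per molecule, named atom indices for each scaffold position), `rmsd`
#'   (per molecule scaffold RMSD to the template) and `scaffold`.
#' @export
align_to_scaffold <- function(mols, scaffold = purine_scaffold()) {
  stopifnot(length(mols) >= 1)
  if (is.character(scaffold)) {
    m <- embed_conformer(list(id = "scaffold", smiles = scaffold))
    heavy <- which(m$atoms$heavy)
    pos <- paste0("A", seq_along(heavy))
    b <- m$bonds
    keep <- b$from %in% heavy & b$to %in% heavy
    scaffold <- structure(list(
      atoms = stats::setNames(m$atoms$element[heavy], pos),
      bonds = data.frame(from = pos[match(b$from[keep], heavy)],
                         to = pos[match(b$to[keep], heavy)])
    ), class = "scaffold")
  }
  matches <- lapply(mols, .scaffold_matches, scaffold = scaffold)
  bad <- vapply(matches, function(m) length(m) == 0L, TRUE)
  if (any(bad)) {
    stop("scaffold not found in: ",
      paste(vapply(mols[bad], `[[`, "", "id"), collapse = ", "))
  }
  template <- mols[[1]]
  tmap <- matches[[1]][[1]]
  tref <- coords(template)[tmap, , drop = FALSE]
  mappings <- vector("list", length(mols))
  rmsds <- numeric(length(mols))
  aligned <- mols
  for (i in seq_along(mols)) {
    best <- NULL
    for (map in matches[[i]]) {
      xyz <- coords(mols[[i]])[map, , drop = FALSE]
      fit <- .kabsch(xyz, tref)
      r <- .rmsd(sweep(xyz %*% fit$rot, 2, fit$trans, `+`) * 1, tref)
      if (is.null(best) || r < best$r) best <- list(map = map, fit = fit, r = r)
    }
    aligned[[i]] <- .transform_molecule(mols[[i]], best$fit$rot, best$fit$trans)
    mappings[[i]] <- best$map
    rmsds[i] <- best$r
  }
  ids <- vapply(mols, `[[`, "", "id")
  names(aligned) <- names(mappings) <- names(rmsds) <- ids
  structure(
    list(molecules = aligned, mappings = mappings, rmsd = rmsds,
         scaffold = scaffold, template_id = ids[[1]]),
    class = "aligned_set"
  )
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf(
    "<aligned_set: %d molecules on a %d-atom scaffold, max scaffold RMSD %.3f A>\n",
    length(x$molecules), length(x$scaffold$atoms), max(x$rmsd)
  ))
  invisible(x)
}

#' Centroid of the substituent attached at a scaffold position
#'
#' Returns the centroid (in the shared frame) of all heavy atoms reachable
#' from the given scaffold position without passing through any other
#' scaffold atom - i.e. the substituent branch rooted there. If the position
#' carries no substituent, the position's own coordinates are returned.
#'
#' @param aligned an `aligned_set`.
#' @param id molecule id.
#' @param position scaffold position name (e.g. `"C2"`, `"C6"`, `"N9"` for
#'   the purine core).
#' @return numeric length-3 vector.
#' @export
substituent_centroid <- function(aligned, id, position) {
  mol <- aligned$molecules[[id]]
  map <- aligned$mappings[[id]]
  if (is.null(mol)) stop("unknown molecule id '", id, "'")
  if (!position %in% names(map)) stop("unknown scaffold position '", position, "'")
  root <- map[[position]]
  core <- setdiff(unname(map), root)
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    f <- mol$bonds$from[k]; t <- mol$bonds$to[k]
    adj[[f]] <- c(adj[[f]], t); adj[[t]] <- c(adj[[t]], f)
  }
  seen <- rep(FALSE, n)
  seen[core] <- TRUE # walls
  seen[root] <- TRUE
  queue <- setdiff(adj[[root]], core)
  branch <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (seen[v]) next
    seen[v] <- TRUE
    branch <- c(branch, v)
    queue <- c(queue, adj[[v]])
  }
  branch <- branch[mol$atoms$heavy[branch]]
  if (!length(branch)) {
    return(as.numeric(coords(mol)[root, ]))
  }
  colMeans(coords(mol)[branch, , drop = FALSE])
}
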