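# STDEV*COEFF contour extraction: the per-grid-point display values behind
# CoMFA contour maps, their favoured/disfavoured regions, and annotation of
# regions relative to substituent positions of a reference compound.

#' STDEV x COEFF display values of a fitted field model
#'
#' For every kept grid column, the product of the PLS coefficient and the
#' column's standard deviation - the quantity CoMFA contour maps display.
#'
#' @param model a `pls_model` fitted on the kept columns of `fm`.
#' @param fm the `field_matrix` the model was fitted on.
#' @return list with components `steric` and `electrostatic`, each a
#'   data.frame(col, grid_index, value); `grid_index` is the 0-based node
#'   index.
#' @export
stdev_coeff_values <- function(model, fm) {
  x <- field_values(fm, filtered = TRUE)
  if (length(model$b) != ncol(x)) {
    stop("model has ", length(model$b), " coefficients but the filtered ",
         "field matrix has ", ncol(x), " columns")
  }
  vals <- model$b * apply(x, 2, stats::sd)
  cn <- colnames(x)
  out <- data.frame(col = cn,
                    grid_index = as.integer(sub("^[SE]:", "", cn)),
                    value = unname(vals), stringsAsFactors = FALSE)
  list(steric = out[grepl("^S:", cn), ],
       electrostatic = out[grepl("^E:", cn), ])
}

#' Extract favoured / disfavoured contour regions
#'
#' Grid points whose display value lies strictly above the `upper_pct`
#' percentile form the favoured set (green for steric, blue for
#' electrostatic with a +1 probe); points strictly below the `lower_pct`
#' percentile form the disfavoured set (yellow / red).
#'
#' @param values one block of [stdev_coeff_values()] (data.frame with
#'   `grid_index`, `value`).
#' @param upper_pct,lower_pct percentile levels (defaults 80 / 20).
#' @param kind `"steric"` or `"electrostatic"` label carried on the result.
#' @return a `contour_set`: list(kind, favoured, disfavoured, levels) where
#'   favoured/disfavoured are data.frames of grid points and values.
#' @export
extract_contours <- function(values, upper_pct = 80, lower_pct = 20,
                             kind = "steric") {
  stopifnot(lower_pct >= 0, upper_pct <= 100, lower_pct < upper_pct)
  v <- values$value
  if (length(unique(v)) <= 1L) {
    warning("all display values equal: empty contour set")
    empty <- values[0, ]
    return(structure(list(kind = kind, favoured = empty, disfavoured = empty,
                          levels = c(lower = NA_real_, upper = NA_real_)),
                     class = "contour_set"))
  }
  up <- stats::quantile(v, upper_pct / 100, names = FALSE)
  lo <- stats::quantile(v, lower_pct / 100, names = FALSE)
  structure(list(
    kind = kind,
    favoured = values[v > up, ],
    disfavoured = values[v < lo, ],
    levels = c(lower = lo, upper = up)
  ), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set (%s): %d favoured, %d disfavoured points>\n",
    x$kind, nrow(x$favoured), nrow(x$disfavoured)))
  invisible(x)
}

# Connected components of grid points under 6-neighbour connectivity.
.grid_regions <- function(grid_index, counts) {
  if (!length(grid_index)) return(list())
  nx <- counts[1]; ny <- counts[2]
  ix <- grid_index %% nx
  iy <- (grid_index %/% nx) %% ny
  iz <- grid_index %/% (nx * ny)
  n <- length(grid_index)
  key <- function(x, y, z) x + nx * (y + ny * z)
  lookup <- stats::setNames(seq_len(n), grid_index)
  offsets <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  edges <- list()
  for (k in seq_len(6)) {
    nb <- key(ix + offsets[k,1], iy + offsets[k,2], iz + offsets[k,3])
    hit <- !is.na(lookup[as.character(nb)])
    if (any(hit)) edges[[length(edges)+1]] <-
      cbind(seq_len(n)[hit], unname(lookup[as.character(nb[hit])]))
  }
  g <- igraph::graph_from_edgelist(
    if (length(edges)) do.call(rbind, edges) else matrix(0L, 0, 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - length(igraph::V(g))))
  comp <- igraph::components(g)$membership[seq_len(n)]
  split(seq_len(n), comp)
}

#' Locate contour regions relative to a reference compound
#'
#' Groups each polarity's grid points into connected regions (6-neighbour
#' connectivity), computes region centroids and sizes, and annotates each
#' region with its distance to the substituent centroids of a reference
#' compound (purine positions C2, C6, N9 by default) and the nearest one.
#'
#' @param cs a `contour_set`.
#' @param aligned the `aligned_set` the fields were computed on.
#' @param grid the `grid_spec`.
#' @param reference id of the reference molecule (default: the template).
#' @param positions scaffold positions to annotate against.
#' @return data.frame, one row per region: polarity, size, centroid
#'   coordinates, one distance column per position, `nearest` label.
#' @export
locate_contours <- function(cs, aligned, grid,
                            reference = aligned$template_id,
                            positions = c("C2", "C6", "N9")) {
  pts <- grid$points
  anchor <- lapply(positions, function(p)
    substituent_centroid(aligned, reference, p))
  names(anchor) <- positions
  one_pol <- function(df, polarity) {
    regs <- .grid_regions(df$grid_index, grid$counts)
    if (!length(regs)) return(NULL)
    do.call(rbind, lapply(regs, function(rows) {
      cen <- colMeans(pts[df$grid_index[rows] + 1L, , drop = FALSE])
      dists <- vapply(anchor, function(a) sqrt(sum((cen - a)^2)), 0)
      out <- data.frame(polarity = polarity, size = length(rows),
                        x = cen[1], y = cen[2], z = cen[3])
      for (p in positions) out[[paste0("dist_", p)]] <- dists[[p]]
      out$nearest <- positions[which.min(dists)]
      out
    }))
  }
  res <- rbind(one_pol(cs$favoured, "favoured"),
               one_pol(cs$disfavoured, "disfavoured"))
  if (is.null(res)) {
    res <- data.frame(polarity = character(0), size = integer(0))
  }
  rownames(res) <- NULL
  res
}
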