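# Persistence helpers: field matrices as (gzipped) CSV, scalar grids as
# OpenDX files for visualization in molecular viewers.

#' Write a field matrix to a gzipped CSV
#'
#' One row per molecule (`id` column), one column per kept grid column
#' (`S:<i>` / `E:<i>`). The grid geometry, probe, cutoff and filter
#' threshold are stored in comment header lines.
#'
#' @param fm a `field_matrix`.
#' @param path output path (".csv.gz" recommended).
#' @export
write_field_matrix <- function(fm, path) {
  x <- field_values(fm, filtered = TRUE)
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# origin %s", paste(fm$grid$origin, collapse = " ")),
    sprintf("# spacing %g", fm$grid$spacing),
    sprintf("# counts %s", paste(fm$grid$counts, collapse = " ")),
    sprintf("# cutoff %g", fm$cutoff),
    sprintf("# threshold %g", fm$threshold)
  ), con)
  utils::write.csv(data.frame(id = fm$ids, x, check.names = FALSE),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a field matrix written by [write_field_matrix()]
#'
#' @param path the CSV (optionally gzipped).
#' @return list(ids, values, origin, spacing, counts, cutoff, threshold);
#'   `values` is the kept-column matrix with `S:`/`E:` column names.
#' @export
read_field_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  num <- function(key) as.numeric(strsplit(sub(paste0("^# ", key, " "), "",
    grep(paste0("^# ", key, " "), hdr, value = TRUE)[1]), " ")[[1]])
  d <- utils::read.csv(text = lines[!grepl("^#", lines)], check.names = FALSE)
  values <- as.matrix(d[, -1, drop = FALSE])
  rownames(values) <- d$id
  list(ids = d$id, values = values, origin = num("origin"),
       spacing = num("spacing"), counts = as.integer(num("counts")),
       cutoff = num("cutoff"), threshold = num("threshold"))
}

#' Export a scalar grid as an OpenDX file
#'
#' Writes values defined on the pipeline's lattice in OpenDX "regular
#' positions, regular connections" format, readable by PyMOL, VMD or
#' Chimera for contour visualization. Grid nodes without a value (filtered
#' columns) are written as `fill`.
#'
#' @param grid a `grid_spec`.
#' @param grid_index 0-based (x-fastest) node indices carrying values.
#' @param values numeric values, parallel to `grid_index`.
#' @param path output file.
#' @param fill value for nodes not listed (default 0).
#' @export
write_opendx <- function(grid, grid_index, values, path, fill = 0) {
  n <- prod(grid$counts)
  full <- rep(fill, n)
  full[grid_index + 1L] <- values
  # OpenDX expects z-fastest ordering; the package lattice is x-fastest
  arr <- array(full, dim = grid$counts)
  full_dx <- as.vector(aperm(arr, c(3, 2, 1)))
  cx <- grid$counts
  lines <- c(
    sprintf("object 1 class gridpositions counts %d %d %d", cx[1], cx[2], cx[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            cx[1], cx[2], cx[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n),
    vapply(split(full_dx, ceiling(seq_len(n) / 3)),
           function(v) paste(format(v, trim = TRUE), collapse = " "), ""),
    'attribute "dep" string "positions"',
    'object "regular positions regular connections" class field',
    'component "positions" value 1',
    'component "connections" value 2',
    'component "data" value 3'
  )
  writeLines(lines, path)
  invisible(path)
}
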