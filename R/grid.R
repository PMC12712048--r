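# Gridded layers (population, vegetation fraction, housing density, WUI class).
#
# A burn_grid is a numeric matrix plus a planar frame: cell (i, j) covers
# [x0 + (j-1)*cell, x0 + j*cell] x [y0 + (i-1)*cell, y0 + i*cell] km, row 1 at
# the bottom.  Cell size defaults to 0.1 km (100 m), the resolution of the
# gridded population product the pipeline emulates.

#' Construct a gridded layer
#'
#' @param values numeric matrix (rows = northing, row 1 southmost).
#' @param cell cell edge length in km (default 0.1 = 100 m).
#' @param x0,y0 planar coordinates of the grid's lower-left corner (km).
#' @param frame a [burn_frame()] tying the planar frame to lon/lat.
#' @return object of class `burn_grid`.
#' @export
burn_grid <- function(values, cell = 0.1, x0 = 0, y0 = 0, frame = burn_frame()) {
  stopifnot(is.matrix(values), cell > 0)
  structure(list(values = values, cell = cell, x0 = x0, y0 = y0, frame = frame),
            class = "burn_grid")
}

#' @export
dim.burn_grid <- function(x) dim(x$values)

#' @export
print.burn_grid <- function(x, ...) {
  cat(sprintf("<burn_grid %d x %d cells, %.0f m resolution, origin (%.1f, %.1f) km>\n",
              nrow(x$values), ncol(x$values), x$cell * 1000, x$x0, x$y0))
  invisible(x)
}

same_grid_frame <- function(a, b) {
  isTRUE(all.equal(a$cell, b$cell)) && isTRUE(all.equal(a$x0, b$x0)) &&
    isTRUE(all.equal(a$y0, b$y0)) && all(dim(a$values) == dim(b$values))
}

#' Cell-centre coordinates of a grid
#' @param grid a [burn_grid()].
#' @return list with vectors `x` (by column) and `y` (by row), km.
#' @export
grid_centers <- function(grid) {
  list(x = grid$x0 + (seq_len(ncol(grid$values)) - 0.5) * grid$cell,
       y = grid$y0 + (seq_len(nrow(grid$values)) - 0.5) * grid$cell)
}

# Logical matrix of cells whose centres lie within `dist_km` of geometry
# (polygon matrix or point c(x, y)); dist_km = 0 means inside/containing cell.
grid_mask_near <- function(grid, geometry, dist_km = 0) {
  ctr <- grid_centers(grid)
  nx <- length(ctr$x); ny <- length(ctr$y)
  px <- rep(ctr$x, each = ny)
  py <- rep(ctr$y, times = nx)
  if (is.null(dim(geometry))) {
    d <- sqrt((px - geometry[1])^2 + (py - geometry[2])^2)
    m <- if (dist_km > 0) d <= dist_km else d <= grid$cell / sqrt(2) + 1e-12
  } else if (dist_km > 0) {
    m <- dist_points_to_polygon(px, py, geometry) <= dist_km
  } else {
    m <- points_in_polygon(px, py, geometry)
  }
  matrix(m, nrow = ny, ncol = nx)
}

#' Write a grid as an ESRI ASCII raster (plain text)
#'
#' @param grid a [burn_grid()].
#' @param path output file path (.asc).
#' @export
write_grid_asc <- function(grid, path) {
  hdr <- c(
    sprintf("ncols %d", ncol(grid$values)),
    sprintf("nrows %d", nrow(grid$values)),
    sprintf("xllcorner %.6f", grid$x0),
    sprintf("yllcorner %.6f", grid$y0),
    sprintf("cellsize %.6f", grid$cell),
    "NODATA_value -9999")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  # ASCII grids store row 1 at the top
  for (i in rev(seq_len(nrow(grid$values)))) {
    writeLines(paste(format(grid$values[i, ], trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII raster written by [write_grid_asc()]
#' @param path file path.
#' @param frame planar frame to attach.
#' @return a [burn_grid()].
#' @export
read_grid_asc <- function(path, frame = burn_frame()) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  hv <- vapply(hdr, function(kv) as.numeric(kv[2]), numeric(1))
  names(hv) <- vapply(hdr, function(kv) tolower(kv[1]), character(1))
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  burn_grid(vals, cell = hv[["cellsize"]], x0 = hv[["xllcorner"]],
            y0 = hv[["yllcorner"]], frame = frame)
}
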