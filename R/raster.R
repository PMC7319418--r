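# Minimal single-band raster container on a regular planar grid.
#
# `values` is a numeric matrix whose first row is the NORTHERN edge of the
# grid (map orientation), so the matrix prints the way the map looks.
# Missing data are NA. Persisted as Esri ASCII grid, a plain-text format.

#' Create a raster
#' @param values numeric matrix, row 1 = north.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize cell edge length in metres.
#' @return a `dc_raster`.
#' @export
dc_raster <- function(values, xll = 0, yll = 0, cellsize = 5) {
  stopifnot(is.matrix(values), cellsize > 0)
  storage.mode(values) <- "double"
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize),
            class = "dc_raster")
}

#' @export
print.dc_raster <- function(x, ...) {
  cat(sprintf("<dc_raster %d x %d @ %gm, origin (%g, %g), range [%g, %g]>\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

raster_nrow <- function(r) nrow(r$values)
raster_ncol <- function(r) ncol(r$values)

#' Cell-centre coordinates of every cell
#' @param r a `dc_raster`.
#' @return list with matrices `x` and `y` of the same shape as the values.
#' @export
raster_xy <- function(r) {
  nr <- raster_nrow(r); nc <- raster_ncol(r)
  x <- matrix(r$xll + (seq_len(nc) - 0.5) * r$cellsize, nr, nc, byrow = TRUE)
  y <- matrix(r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize, nr, nc)
  list(x = x, y = y)
}

#' Row/column of the cells containing points
#' @param r raster; `x`, `y` point coordinates.
#' @param x,y coordinates.
#' @return two-column matrix (row, col); NA outside the grid.
#' @export
raster_rowcol <- function(r, x, y) {
  col <- floor((x - r$xll) / r$cellsize) + 1L
  row <- raster_nrow(r) - floor((y - r$yll) / r$cellsize)
  bad <- col < 1L | col > raster_ncol(r) | row < 1L | row > raster_nrow(r)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at points (nearest cell)
#' @param r raster.
#' @param x,y point coordinates.
#' @return numeric vector, NA outside the grid.
#' @export
raster_extract <- function(r, x, y) {
  rc <- raster_rowcol(r, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Blank raster covering an extent
#' @param xmin,ymin,xmax,ymax extent.
#' @param cellsize cell size.
#' @param value fill value.
#' @return a `dc_raster` whose extent covers the box with whole cells.
#' @export
raster_template <- function(xmin, ymin, xmax, ymax, cellsize = 5, value = NA_real_) {
  nc <- max(1L, ceiling((xmax - xmin) / cellsize))
  nr <- max(1L, ceiling((ymax - ymin) / cellsize))
  dc_raster(matrix(value, nr, nc), xll = xmin, yll = ymin, cellsize = cellsize)
}

#' Nearest-neighbour resampling onto a template grid
#'
#' Used for categorical and banded data, where interpolation would invent
#' classes. Cells of the template falling outside the source get NA.
#' @param r source raster.
#' @param template raster defining the target grid.
#' @return resampled `dc_raster` on the template grid.
#' @export
raster_resample_nn <- function(r, template) {
  xy <- raster_xy(template)
  vals <- raster_extract(r, as.vector(xy$x), as.vector(xy$y))
  dc_raster(matrix(vals, raster_nrow(template), raster_ncol(template)),
            xll = template$xll, yll = template$yll, cellsize = template$cellsize)
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    raster_nrow(a) == raster_nrow(b) && raster_ncol(a) == raster_ncol(b)
}

## -- Esri ASCII grid I/O -------------------------------------------------

#' Write a raster as Esri ASCII grid
#' @param r raster.
#' @param path output file.
#' @param nodata value written for NA cells.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", raster_ncol(r)),
    sprintf("nrows %d", raster_nrow(r)),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$cellsize),
    sprintf("NODATA_value %g", nodata)
  ), con)
  v <- r$values
  v[is.na(v)] <- nodata
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an Esri ASCII grid
#' @param path file path.
#' @return a `dc_raster` (nodata cells become NA).
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6L))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA_real_
  dc_raster(v, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
            cellsize = val[["cellsize"]])
}
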