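#' Planar raster grid
#'
#' A minimal single-band raster on a planar grid in meters: a numeric matrix
#' plus an origin and a cell size. Row 1 is the northernmost row; cell values
#' are looked up at cell centers. This is the geometric substrate for the DEM,
#' the land-use mosaic and all buffer work.
#'
#' @param values numeric or integer matrix (ny rows, nx columns); row 1 is the
#'   northernmost row.
#' @param xll,yll planar coordinates (m) of the lower-left corner of the grid.
#' @param res cell size in meters (square cells).
#' @return an object of class `gw_raster`.
#' @export
gw_raster <- function(values, xll = 0, yll = 0, res = 10) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (res <= 0) stop("`res` must be > 0", call. = FALSE)
  structure(
    list(values = values, xll = xll, yll = yll, res = res,
         ny = nrow(values), nx = ncol(values)),
    class = "gw_raster"
  )
}

#' @export
print.gw_raster <- function(x, ...) {
  cat(sprintf("<gw_raster> %d x %d cells, %g m resolution\n", x$ny, x$nx, x$res))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g] m\n",
              x$xll, x$xll + x$nx * x$res, x$yll, x$yll + x$ny * x$res))
  cat(sprintf("  values: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.gw_raster <- function(x) c(x$ny, x$nx)

#' Coordinate/index conversions
#'
#' Cells use half-open indexing `[row, row + 1)` from the top-left origin;
#' `cell_center()` returns the planar coordinates of a cell's center and
#' `cell_index()` the (row, col) pair containing a coordinate.
#'
#' @param r a [gw_raster()].
#' @param row,col 1-based cell indices.
#' @return `cell_center()`: a list with `x` and `y`; `cell_index()`: a list
#'   with `row` and `col`.
#' @export
cell_center <- function(r, row, col) {
  list(x = r$xll + (col - 0.5) * r$res,
       y = r$yll + (r$ny - row + 0.5) * r$res)
}

#' @rdname cell_center
#' @param x,y planar coordinates in meters.
#' @export
cell_index <- function(r, x, y) {
  col <- floor((x - r$xll) / r$res) + 1L
  row <- r$ny - floor((y - r$yll) / r$res)
  if (any(col < 1L | col > r$nx | row < 1L | row > r$ny))
    stop("coordinate outside raster extent", call. = FALSE)
  list(row = as.integer(row), col = as.integer(col))
}

#' Raster value at planar coordinates
#' @inheritParams cell_center
#' @param x,y planar coordinates in meters.
#' @return the cell value at the cell containing (x, y).
#' @export
raster_value_at <- function(r, x, y) {
  idx <- cell_index(r, x, y)
  r$values[cbind(idx$row, idx$col)]
}

#' Read and write Esri ASCII grids
#'
#' Plain-text raster exchange format (`.asc`): a 6-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values, northernmost row first. Round-trips a [gw_raster()].
#'
#' @param r a [gw_raster()].
#' @param path file path.
#' @param digits significant digits written for floating-point grids.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [gw_raster()].
#' @export
write_ascii_grid <- function(r, path, digits = 7) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$nx),
    sprintf("nrows %d", r$ny),
    sprintf("xllcorner %.10g", r$xll),
    sprintf("yllcorner %.10g", r$yll),
    sprintf("cellsize %.10g", r$res),
    "NODATA_value -9999"
  ), con)
  vals <- format(r$values, digits = digits, trim = TRUE, scientific = FALSE)
  writeLines(apply(vals, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1L))
  val <- as.numeric(vapply(kv, `[`, "", 2L))
  names(val) <- key
  nx <- as.integer(val[["ncols"]]); ny <- as.integer(val[["nrows"]])
  body <- scan(path, skip = 6L, quiet = TRUE)
  if (length(body) != nx * ny) stop("grid body does not match header dims", call. = FALSE)
  m <- matrix(body, nrow = ny, ncol = nx, byrow = TRUE)
  gw_raster(m, xll = val[["xllcorner"]], yll = val[["yllcorner"]],
            res = val[["cellsize"]])
}
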