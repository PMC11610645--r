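#' Default buffer radii
#'
#' The thirteen radii (m) of the multi-scale analysis, from 10 m to 5 km.
#' @return numeric vector of radii in meters.
#' @export
default_buffer_sizes <- function()
  c(10, 20, 50, 100, 200, 400, 600, 800, 1000, 2000, 3000, 4000, 5000)

check_same_geometry <- function(a, b) {
  if (a$ny != b$ny || a$nx != b$nx || a$res != b$res ||
      a$xll != b$xll || a$yll != b$yll)
    stop("rasters are not on the same grid (geometry error)", call. = FALSE)
  invisible(TRUE)
}

new_buffer_region <- function(site_id, size, type, cells, res, truncated) {
  structure(list(site_id = site_id, size = size, type = type, cells = cells,
                 n_cells = nrow(cells), area = nrow(cells) * res^2,
                 truncated = truncated),
            class = "buffer_region")
}

#' @export
print.buffer_region <- function(x, ...) {
  cat(sprintf("<buffer_region> site %s, %s buffer, radius %g m: %d cells (%.3g m^2)%s\n",
              as.character(x$site_id), x$type, x$size, x$n_cells, x$area,
              if (x$truncated) " [truncated at raster edge]" else ""))
  invisible(x)
}

site_xye <- function(site, dem) {
  x <- site$x[1]; y <- site$y[1]
  elev <- if (!is.null(site$elevation_m) && is.finite(site$elevation_m[1]))
    site$elevation_m[1] else raster_value_at(dem, x, y)
  list(x = x, y = y, elev = elev,
       id = if (!is.null(site$site_id)) site$site_id[1] else NA)
}

#' Round buffer around a site
#'
#' All raster cells whose centers lie within `size` meters of the site
#' coordinate; the site's own cell is always included, so a radius smaller
#' than half the resolution yields exactly that cell.
#'
#' @param site a one-row data frame (or list) with `x`, `y` (and optionally
#'   `site_id`, `elevation_m`).
#' @param size buffer radius in meters.
#' @param raster a [gw_raster()] supplying the grid geometry.
#' @return a `buffer_region` with fields `cells` (n x 2 matrix of row, col),
#'   `area` (m^2) and a `truncated` flag raised when the buffer extends
#'   beyond the raster bounds (the caller decides whether to drop the site).
#' @export
make_round_buffer <- function(site, size, raster) {
  stopifnot(inherits(raster, "gw_raster"))
  if (size <= 0) stop("`size` must be > 0", call. = FALSE)
  s <- site_xye(site, raster)
  res <- .region_cells_cpp(raster$values, s$x, s$y, s$elev, size, FALSE,
                           raster$xll, raster$yll, raster$res, Inf, Inf, 8L)
  new_buffer_region(s$id, size, "round", res$cells, raster$res, res$truncated)
}

#' Topography-restricted catchment buffer
#'
#' Subset of the round buffer approximating the surface drainage area of a
#' site: cells whose elevation is at least the site elevation minus `drop_m`
#' (the drop absorbs local small-scale surface maxima), restricted to the
#' gap-bridged connected component containing the site cell. Two qualifying
#' cells are connected when their centers are within `gap_m` of each other,
#' so higher-lying areas separated from the site by more than `gap_m` are
#' discarded as not draining toward it. The site cell is always included.
#'
#' `drop_m = Inf` reduces the catchment to the full round buffer;
#' `gap_m = Inf` waives connectivity (every qualifying cell is kept);
#' `gap_m = 0` falls back to plain 4- or 8-neighborhood adjacency
#' (`connectivity`).
#'
#' @inheritParams make_round_buffer
#' @param dem a [gw_raster()] of elevations covering the buffer.
#' @param drop_m elevation tolerance below the site (m), default 5.
#' @param gap_m bridging distance between qualifying cells (m), default 50.
#' @param connectivity 4 or 8; only used when `gap_m` is below the cell size.
#' @return a `buffer_region`; see [make_round_buffer()].
#' @export
delineate_catchment_buffer <- function(site, size, dem, drop_m = 5, gap_m = 50,
                                       connectivity = 8L) {
  stopifnot(inherits(dem, "gw_raster"))
  if (size <= 0) stop("`size` must be > 0", call. = FALSE)
  if (drop_m < 0 || gap_m < 0) stop("`drop_m` and `gap_m` must be >= 0", call. = FALSE)
  s <- site_xye(site, dem)
  res <- .region_cells_cpp(dem$values, s$x, s$y, s$elev, size, TRUE,
                           dem$xll, dem$yll, dem$res, drop_m, gap_m,
                           as.integer(connectivity))
  new_buffer_region(s$id, size, "catchment", res$cells, dem$res, res$truncated)
}

#' Land-use proportions within a buffer region
#'
#' Per-class cell-count proportions of the five classes over the region.
#'
#' @param region a `buffer_region`.
#' @param landuse a [gw_raster()] of class codes 1..5 (see [reclassify()]).
#' @param class_map optional character vector of class labels in code order;
#'   defaults to [landuse_classes()].
#' @return named numeric vector of fractions summing to 1.
#' @export
extract_proportions <- function(region, landuse, class_map = landuse_classes()) {
  stopifnot(inherits(region, "buffer_region"), inherits(landuse, "gw_raster"))
  if (region$n_cells == 0) stop("empty buffer region (extraction error)", call. = FALSE)
  codes <- landuse$values[region$cells]
  bad <- setdiff(unique(codes), seq_along(class_map))
  if (length(bad))
    stop("unmapped land-use code(s) in region: ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- tabulate(codes, nbins = length(class_map))
  stats::setNames(counts / region$n_cells, class_map)
}

#' Reclassify raw land-use codes to the five analysis classes
#'
#' @param raw a [gw_raster()] of arbitrary integer codes.
#' @param mapping named vector mapping raw codes (names) to class labels or
#'   codes 1..5 (values), total over every code present in the raster.
#' @return a [gw_raster()] with codes 1..5 in [landuse_classes()] order.
#' @export
reclassify <- function(raw, mapping) {
  stopifnot(inherits(raw, "gw_raster"))
  cls <- landuse_classes()
  target <- if (is.character(mapping)) match(mapping, cls) else as.integer(mapping)
  if (anyNA(target) || any(target < 1 | target > 5))
    stop("mapping values must be the five class labels or codes 1..5", call. = FALSE)
  names(target) <- names(mapping)
  present <- unique(as.vector(raw$values))
  missing <- setdiff(as.character(present), names(target))
  if (length(missing))
    stop("unmapped input code(s): ", paste(missing, collapse = ", "), call. = FALSE)
  out <- matrix(target[as.character(raw$values)], raw$ny, raw$nx)
  gw_raster(out, xll = raw$xll, yll = raw$yll, res = raw$res)
}

#' Land-use proportions for many sites, sizes and buffer types
#'
#' Bulk extraction: for every site and every requested (size, type)
#' combination, delineates the buffer and tallies class proportions. This is
#' the input table of the multi-scale scan.
#'
#' @param sites data frame with `site_id`, `x`, `y` (and optionally
#'   `elevation_m`; read from the DEM otherwise).
#' @param dem,landuse [gw_raster()] layers on the same grid; `landuse` holds
#'   codes 1..5.
#' @param sizes buffer radii in meters.
#' @param types subset of `c("round", "catchment")`.
#' @inheritParams delineate_catchment_buffer
#' @return data frame with one row per site x size x type: `site_id`,
#'   `size_m`, `buffer_type`, one fraction column per class, `n_cells`,
#'   `area_m2`, `truncated`.
#' @export
landuse_proportions <- function(sites, dem, landuse,
                                sizes = default_buffer_sizes(),
                                types = c("round", "catchment"),
                                drop_m = 5, gap_m = 50, connectivity = 8L) {
  stopifnot(inherits(dem, "gw_raster"), inherits(landuse, "gw_raster"))
  check_same_geometry(dem, landuse)
  types <- match.arg(types, c("round", "catchment"), several.ok = TRUE)
  cls <- landuse_classes()
  elev <- if ("elevation_m" %in% names(sites)) sites$elevation_m
          else raster_value_at(dem, sites$x, sites$y)
  storage.mode(landuse$values) <- "integer"
  out <- vector("list", length(sizes) * length(types))
  k <- 0L
  for (type in types) for (size in sizes) {
    res <- .region_class_counts_cpp(dem$values, landuse$values, length(cls),
                                    sites$x, sites$y, elev, size,
                                    type == "catchment", dem$xll, dem$yll,
                                    dem$res, drop_m, gap_m,
                                    as.integer(connectivity))
    props <- res$counts / res$ncells
    colnames(props) <- cls
    k <- k + 1L
    out[[k]] <- data.frame(site_id = sites$site_id, size_m = size,
                           buffer_type = type, props,
                           n_cells = res$ncells,
                           area_m2 = res$ncells * dem$res^2,
                           truncated = res$truncated)
  }
  do.call(rbind, out)
}

#' Long-format view of a proportions table
#'
#' Reshapes the wide output of [landuse_proportions()] to one row per
#' (site, size, type, class) for CSV exchange.
#'
#' @param props output of [landuse_proportions()].
#' @return data frame with columns `site_id`, `size_m`, `buffer_type`,
#'   `class`, `proportion`.
#' @export
proportions_long <- function(props) {
  cls <- intersect(landuse_classes(), names(props))
  out <- do.call(rbind, lapply(cls, function(cl)
    data.frame(site_id = props$site_id, size_m = props$size_m,
               buffer_type = props$buffer_type, class = cl,
               proportion = props[[cl]])))
  out[order(out$site_id, out$size_m, out$buffer_type, out$class), , drop = FALSE]
}
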