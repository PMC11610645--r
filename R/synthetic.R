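#' @useDynLib stygoscale, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rbinom rgamma rlnorm plogis fft sd quantile
NULL

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic landscape configuration
#'
#' Parameters of the Gaussian-random-field landscape generator: grid size and
#' resolution, terrain amplitude and correlation length, land-use mosaic
#' correlation length (controls patch size) and the target class proportions.
#'
#' @param nx,ny cell counts (default 1500 x 1500, i.e. 15 x 15 km at 10 m).
#' @param resolution cell size in meters.
#' @param dem_amplitude standard deviation of the terrain elevation field (m).
#' @param dem_corr_length correlation length of the terrain field (m).
#' @param landuse_corr_length correlation length of the mosaic field (m);
#'   larger values give larger land-use patches.
#' @param class_proportions named numeric vector over
#'   `c("forest", "pasture", "crop", "construction", "other")` summing to 1.
#' @param base_elevation mean elevation (m) added to the terrain field.
#' @param seed integer seed; all generators are bit-reproducible given the
#'   configuration.
#' @return a list of class `landscape_config`.
#' @export
landscape_config <- function(nx = 1500L, ny = 1500L, resolution = 10,
                             dem_amplitude = 50, dem_corr_length = 1000,
                             landuse_corr_length = 300,
                             class_proportions = c(forest = 0.35, pasture = 0.2,
                                                   crop = 0.2, construction = 0.1,
                                                   other = 0.15),
                             base_elevation = 500, seed = 1L) {
  if (nx < 1 || ny < 1) stop("grid dimensions must be positive", call. = FALSE)
  if (resolution <= 0) stop("`resolution` must be > 0", call. = FALSE)
  if (dem_corr_length <= 0 || landuse_corr_length <= 0)
    stop("correlation lengths must be > 0", call. = FALSE)
  if (dem_amplitude < 0) stop("`dem_amplitude` must be >= 0", call. = FALSE)
  cls <- landuse_classes()
  if (!setequal(names(class_proportions), cls))
    stop("`class_proportions` must be named over: ", paste(cls, collapse = ", "),
         call. = FALSE)
  class_proportions <- class_proportions[cls]
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("`class_proportions` must sum to 1", call. = FALSE)
  if (any(class_proportions < 0)) stop("class proportions must be >= 0", call. = FALSE)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), resolution = resolution,
                 dem_amplitude = dem_amplitude, dem_corr_length = dem_corr_length,
                 landuse_corr_length = landuse_corr_length,
                 class_proportions = class_proportions,
                 base_elevation = base_elevation, seed = as.integer(seed)),
            class = "landscape_config")
}

#' Land-use class labels and codes
#'
#' The five aggregated land-use classes, in code order 1..5.
#' @return character vector of class labels.
#' @export
landuse_classes <- function() c("forest", "pasture", "crop", "construction", "other")

# Stationary Gaussian random field on a periodic grid via circulant embedding:
# white noise filtered in the Fourier domain by the square root of the
# spectral density of a squared-exponential correlation with length L.
# Returned field is standardized to mean 0, sd 1 (constant 0 if degenerate).
gaussian_field <- function(ny, nx, res, corr_length) {
  dx <- res * pmin(0:(nx - 1), nx - (0:(nx - 1)))
  dy <- res * pmin(0:(ny - 1), ny - (0:(ny - 1)))
  d2 <- outer(dy^2, dx^2, "+")
  s <- Re(stats::fft(exp(-d2 / (2 * corr_length^2))))
  s[s < 0] <- 0
  z <- stats::fft(matrix(stats::rnorm(ny * nx), ny, nx))
  f <- Re(stats::fft(z * sqrt(s), inverse = TRUE)) / (ny * nx)
  sdev <- stats::sd(f)
  if (sdev > 0) (f - mean(f)) / sdev else f * 0
}

#' Generate a synthetic digital elevation model
#'
#' A spatially autocorrelated elevation surface: a Gaussian random field with
#' squared-exponential correlation of length `dem_corr_length`, scaled to
#' `dem_amplitude` (standard deviation in meters) around `base_elevation`.
#'
#' @param cfg a [landscape_config()].
#' @return a [gw_raster()] of elevations in meters.
#' @export
generate_dem <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  f <- with_seed(cfg$seed, gaussian_field(cfg$ny, cfg$nx, cfg$resolution,
                                          cfg$dem_corr_length))
  gw_raster(cfg$base_elevation + cfg$dem_amplitude * f, res = cfg$resolution)
}

#' Generate a synthetic land-use mosaic
#'
#' A second, independent Gaussian random field (correlation length
#' `landuse_corr_length`) is sliced by rank into the five classes at the
#' configured proportions, producing contiguous patches whose realized class
#' fractions match `class_proportions` to within one cell per class.
#'
#' @param cfg a [landscape_config()].
#' @return a [gw_raster()] of integer class codes 1..5 in the order of
#'   [landuse_classes()].
#' @export
generate_landuse <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  f <- with_seed(cfg$seed + 1L, gaussian_field(cfg$ny, cfg$nx, cfg$resolution,
                                               cfg$landuse_corr_length))
  ncell <- length(f)
  # Band order along the field axis: forest at one extreme, the agricultural
  # classes beyond the unconstrained "other" band. Classes adjacent in field
  # value share patch borders, so this order makes pasture and crop
  # anticorrelate with forest across buffers -- the forest-agriculture
  # contrast of the system being emulated.
  band_order <- c("forest", "other", "pasture", "crop", "construction")
  cls <- landuse_classes()
  pp <- cfg$class_proportions[band_order]
  counts <- diff(c(0, round(cumsum(pp) * ncell)))
  codes <- rep.int(match(band_order, cls), counts)
  out <- integer(ncell)
  out[order(f)] <- codes
  gw_raster(matrix(out, cfg$ny, cfg$nx), res = cfg$resolution)
}

#' Ground-truth response configuration
#'
#' The data-generating model for site responses: the true scale of effect and
#' buffer type at which forest cover drives amphipod presence, the logistic
#' coefficients, the Gamma log-link nitrate model, and the protection-zone
#' extent distribution.
#'
#' Defaults mirror the study system this generator emulates: a 600 m
#' catchment-buffer scale of effect, nitrate slopes of +0.015 (crop) and
#' -0.0070 (forest) per percentage point of coverage, a 327 m median
#' protection-zone extent with log-scale spread chosen so about two thirds of
#' zones fall below 400 m, and roughly one-in-three prevalence.
#'
#' @param true_scale buffer radius (m) at which the presence model acts.
#' @param true_buffer_type `"catchment"` or `"round"`.
#' @param beta0 logit intercept of the presence model.
#' @param beta_forest logit slope per percentage point of forest cover.
#' @param nitrate_intercept log-scale intercept of the nitrate model
#'   (default `log(15)` mg/L at zero crop and forest cover).
#' @param nitrate_beta_crop,nitrate_beta_forest log-scale slopes per
#'   percentage point of crop / forest cover.
#' @param nitrate_shape Gamma shape parameter of the nitrate draws.
#' @param zone_median median protection-zone extent (m).
#' @param zone_log_sd log-scale SD of the (log-normal) zone extents.
#' @param n_sites number of extraction sites to place.
#' @param min_spacing minimum pairwise site distance (m).
#' @param seed integer seed for site placement and response draws.
#' @return a list of class `truth_config`.
#' @export
truth_config <- function(true_scale = 600, true_buffer_type = "catchment",
                         beta0 = -2.0, beta_forest = 0.04,
                         nitrate_intercept = log(15),
                         nitrate_beta_crop = 0.015, nitrate_beta_forest = -0.0070,
                         nitrate_shape = 4, zone_median = 327, zone_log_sd = 0.46,
                         n_sites = 300L, min_spacing = 200, seed = 1L) {
  true_buffer_type <- match.arg(true_buffer_type, c("catchment", "round"))
  if (true_scale <= 0) stop("`true_scale` must be > 0", call. = FALSE)
  if (n_sites < 10) stop("`n_sites` must be >= 10", call. = FALSE)
  if (zone_median <= 0) stop("`zone_median` must be > 0", call. = FALSE)
  if (zone_log_sd < 0) stop("`zone_log_sd` must be >= 0", call. = FALSE)
  if (nitrate_shape <= 0) stop("`nitrate_shape` must be > 0", call. = FALSE)
  structure(list(true_scale = true_scale, true_buffer_type = true_buffer_type,
                 beta0 = beta0, beta_forest = beta_forest,
                 nitrate_intercept = nitrate_intercept,
                 nitrate_beta_crop = nitrate_beta_crop,
                 nitrate_beta_forest = nitrate_beta_forest,
                 nitrate_shape = nitrate_shape, zone_median = zone_median,
                 zone_log_sd = zone_log_sd, n_sites = as.integer(n_sites),
                 min_spacing = min_spacing, seed = as.integer(seed)),
            class = "truth_config")
}

#' Place extraction sites on a landscape
#'
#' Seeded rejection sampling of site coordinates with a minimum pairwise
#' spacing. When an `edge_margin` is requested (so that the largest buffer
#' fits inside the raster) and the inset area is large enough to hold the
#' sites, placement is restricted to it and `edge_ok` is `TRUE`; otherwise
#' the whole extent is used and sites closer than `edge_margin` to an edge
#' are flagged `edge_ok = FALSE`.
#'
#' @param n number of sites.
#' @param dem a [gw_raster()] of elevations; site elevation is read from it.
#' @param min_spacing minimum pairwise distance in meters.
#' @param seed integer seed.
#' @param edge_margin required clearance (m) from the raster edge, typically
#'   the largest buffer radius to be analyzed.
#' @param max_tries placement attempts per site before giving up.
#' @return a data frame with columns `site_id`, `x`, `y`, `elevation_m`,
#'   `edge_ok`.
#' @export
place_sites <- function(n, dem, min_spacing, seed = 1L, edge_margin = 0,
                        max_tries = 200L) {
  stopifnot(inherits(dem, "gw_raster"))
  w <- dem$nx * dem$res; h <- dem$ny * dem$res
  x0 <- dem$xll; y0 <- dem$yll
  inset <- c(x0 + edge_margin, x0 + w - edge_margin,
             y0 + edge_margin, y0 + h - edge_margin)
  # area heuristic: each site excludes at most a quarter-disc of packing area
  inset_ok <- edge_margin > 0 &&
    (inset[2] - inset[1]) > min_spacing && (inset[4] - inset[3]) > min_spacing &&
    (inset[2] - inset[1]) * (inset[4] - inset[3]) > 2 * n * min_spacing^2
  lim <- if (inset_ok) inset else c(x0, x0 + w, y0, y0 + h)
  if (n > 1 && (lim[2] - lim[1]) * (lim[4] - lim[3]) < n * min_spacing^2 * pi / 8)
    stop("site packing infeasible: grid too small for n sites at this spacing",
         call. = FALSE)
  with_seed(seed, {
    xs <- numeric(n); ys <- numeric(n); placed <- 0L
    tries <- 0L
    while (placed < n) {
      if (tries >= max_tries * n)
        stop("site packing failed after bounded retries", call. = FALSE)
      cx <- stats::runif(1, lim[1], lim[2]); cy <- stats::runif(1, lim[3], lim[4])
      tries <- tries + 1L
      if (placed == 0L ||
          min((xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2) >=
            min_spacing^2) {
        placed <- placed + 1L
        xs[placed] <- cx; ys[placed] <- cy
      }
    }
    edge_ok <- if (inset_ok) rep(TRUE, n) else
      (xs - x0 >= edge_margin & x0 + w - xs >= edge_margin &
       ys - y0 >= edge_margin & y0 + h - ys >= edge_margin)
    data.frame(site_id = seq_len(n), x = xs, y = ys,
               elevation_m = raster_value_at(dem, xs, ys),
               edge_ok = edge_ok)
  })
}

#' Simulate amphipod presence/absence at sites
#'
#' Presence follows a logistic model on the percentage of forest cover within
#' the buffer of the configured true scale and type:
#' `P(presence) = plogis(beta0 + beta_forest * forest_pct)`. Sites whose true
#' buffer is truncated by the raster edge get `NA` presence and are flagged.
#'
#' @param sites data frame from [place_sites()].
#' @param dem,landuse [gw_raster()] layers on the same grid.
#' @param truth a [truth_config()].
#' @return `sites` with added columns `forest_pct_true` and `presence`.
#' @export
simulate_presence <- function(sites, dem, landuse, truth) {
  stopifnot(inherits(truth, "truth_config"))
  prop <- landuse_proportions(sites, dem, landuse, sizes = truth$true_scale,
                              types = truth$true_buffer_type)
  ok <- !prop$truncated
  fpct <- ifelse(ok, 100 * prop$forest, NA_real_)
  p <- stats::plogis(truth$beta0 + truth$beta_forest * fpct)
  pres <- with_seed(truth$seed + 10L,
                    ifelse(is.na(p), NA_integer_, stats::rbinom(nrow(sites), 1L, ifelse(is.na(p), 0.5, p))))
  sites$forest_pct_true <- fpct
  sites$presence <- pres
  if (any(!ok))
    warning(sum(!ok), " site(s) excluded: true-scale buffer truncated by raster edge")
  sites
}

#' Simulate nitrate concentrations at sites
#'
#' Gamma draws with log-link mean
#' `exp(intercept + beta_crop * crop_pct + beta_forest * forest_pct)` on
#' coverage percentages within the true-scale buffer.
#'
#' @inheritParams simulate_presence
#' @return `sites` with added column `nitrate_mg_l` (strictly positive).
#' @export
simulate_nitrate <- function(sites, dem, landuse, truth) {
  stopifnot(inherits(truth, "truth_config"))
  prop <- landuse_proportions(sites, dem, landuse, sizes = truth$true_scale,
                              types = truth$true_buffer_type)
  ok <- !prop$truncated
  mu <- exp(truth$nitrate_intercept +
            truth$nitrate_beta_crop * 100 * prop$crop +
            truth$nitrate_beta_forest * 100 * prop$forest)
  mu[!ok] <- NA_real_
  nit <- with_seed(truth$seed + 20L, {
    draws <- stats::rgamma(nrow(sites), shape = truth$nitrate_shape,
                           scale = ifelse(is.na(mu), 1, mu) / truth$nitrate_shape)
    ifelse(is.na(mu), NA_real_, draws)
  })
  sites$nitrate_mg_l <- nit
  sites
}

#' Simulate protection-zone extents
#'
#' Log-normal extents with the configured median and log-scale SD: positive
#' and right-skewed, as regulatory zone extents of a few hundred meters are.
#'
#' @param n number of zones.
#' @param zone_median median extent (m).
#' @param zone_log_sd log-scale SD; 0 gives all extents equal to the median.
#' @param seed integer seed.
#' @return numeric vector of extents in meters.
#' @export
simulate_protection_zones <- function(n, zone_median = 327, zone_log_sd = 0.46,
                                      seed = 1L) {
  if (zone_median <= 0) stop("`zone_median` must be > 0", call. = FALSE)
  if (zone_log_sd < 0) stop("`zone_log_sd` must be >= 0", call. = FALSE)
  with_seed(seed, stats::rlnorm(n, meanlog = log(zone_median), sdlog = zone_log_sd))
}

#' Write a site table to CSV
#'
#' Columns: `site_id, x, y, elevation_m, presence, nitrate_mg_l,
#' zone_extent_m` (missing response columns are written as empty).
#'
#' @param sites site data frame.
#' @param path output CSV path.
#' @return `path` invisibly.
#' @export
write_sites_csv <- function(sites, path) {
  cols <- c("site_id", "x", "y", "elevation_m", "presence", "nitrate_mg_l",
            "zone_extent_m")
  for (cl in setdiff(cols, names(sites))) sites[[cl]] <- NA
  utils::write.csv(sites[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) utils::read.csv(path)
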