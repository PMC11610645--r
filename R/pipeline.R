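#' Pipeline run configuration
#'
#' Bundles the landscape and ground-truth configurations with the analysis
#' settings of every downstream stage. Per-stage seeds are derived from the
#' master seed by drawing one integer per stage (in fixed stage order) from
#' a generator seeded with the master seed, so any stage can be re-run in
#' isolation; all derived seeds are recorded in the run manifest.
#'
#' @param landscape a [landscape_config()].
#' @param truth a [truth_config()].
#' @param scan_sizes buffer radii (m) scanned; the desk-scale default covers
#'   100-2000 m around the true 600 m scale.
#' @param scan_types buffer types scanned.
#' @param scan_classes land-use classes scanned.
#' @param scan_reps,scan_frac subsampling settings for the pseudo-R-squared
#'   SD (`scan_reps = 0` disables subsampling).
#' @param model_size,model_type buffer at which proportions feed the spatial
#'   models and the composition comparison (default 600 m catchment).
#' @param zone_interval scale-of-effect interval (m) compared against the
#'   protection-zone extents.
#' @param n_random number of random reference sites (`NULL`: as many as
#'   sampled sites).
#' @param seed master seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(landscape = landscape_config(),
                       truth = truth_config(),
                       scan_sizes = c(100, 200, 400, 600, 800, 1000, 2000),
                       scan_types = c("round", "catchment"),
                       scan_classes = c("forest", "pasture", "crop"),
                       scan_reps = 200L, scan_frac = 0.7,
                       model_size = 600, model_type = "catchment",
                       zone_interval = c(400, 1000),
                       n_random = NULL, seed = 1L) {
  stopifnot(inherits(landscape, "landscape_config"), inherits(truth, "truth_config"))
  if (!truth$true_scale %in% scan_sizes)
    warning("true scale ", truth$true_scale, " m is not among the scanned sizes")
  stages <- c("landscape", "sites", "responses", "scan", "zones", "models",
              "random_sites")
  stage_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            length(stages)))
  names(stage_seeds) <- stages
  structure(list(landscape = landscape, truth = truth, scan_sizes = scan_sizes,
                 scan_types = scan_types, scan_classes = scan_classes,
                 scan_reps = as.integer(scan_reps), scan_frac = scan_frac,
                 model_size = model_size, model_type = model_type,
                 zone_interval = zone_interval, n_random = n_random,
                 seed = as.integer(seed), stage_seeds = stage_seeds),
            class = "run_config")
}

# Rolling polynomial hash (mod the Mersenne prime 2^31 - 1) of a character
# vector, as hex; identifies the config in the manifest without external
# digest dependencies. All arithmetic stays exact in doubles.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline on a synthetic landscape
#'
#' Orchestrates: landscape simulation -> site placement and responses ->
#' buffer extraction -> multi-scale GLM scan and peak scale -> protection
#' zone summary -> spatial mixed models (nitrate and presence) -> sampled
#' versus random composition comparison. All outputs are written as CSV or
#' plain-text reports under `out_dir` together with a manifest (config hash,
#' derived seeds, package version); identical configurations yield identical
#' outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param fit_models fit the spatial mixed models (the slowest stage).
#' @return a list with elements `sites`, `proportions`, `scan`, `peak`,
#'   `zones`, `nitrate_fits`, `presence_fit`, `comparison`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, fit_models = TRUE) {
  stopifnot(inherits(config, "run_config"))
  ss <- config$stage_seeds
  lc <- config$landscape
  lc$seed <- ss[["landscape"]]
  truth <- config$truth
  truth$seed <- ss[["responses"]]

  # --- stage 1: landscape -------------------------------------------------
  dem <- generate_dem(lc)
  landuse <- generate_landuse(lc)

  # --- stage 2: sites and responses --------------------------------------
  margin <- max(config$scan_sizes, config$model_size, truth$true_scale)
  sites <- place_sites(truth$n_sites, dem, truth$min_spacing,
                       seed = ss[["sites"]], edge_margin = margin)
  sites <- simulate_presence(sites, dem, landuse, truth)
  sites <- simulate_nitrate(sites, dem, landuse, truth)
  sites$zone_extent_m <- simulate_protection_zones(
    nrow(sites), truth$zone_median, truth$zone_log_sd, seed = ss[["zones"]])

  # --- stage 3: buffers ---------------------------------------------------
  sizes <- sort(unique(c(config$scan_sizes, config$model_size)))
  props <- landuse_proportions(sites, dem, landuse, sizes = sizes,
                               types = unique(c(config$scan_types,
                                                config$model_type)))

  # --- stage 4: scan and peak scale --------------------------------------
  scan <- scale_scan(sites, props, sizes = config$scan_sizes,
                     types = config$scan_types, classes = config$scan_classes,
                     reps = config$scan_reps, frac = config$scan_frac,
                     seed = ss[["scan"]])
  peak <- peak_scale(scan)

  # --- stage 5: protection zones -----------------------------------------
  zones <- zone_summary(sites$zone_extent_m, config$zone_interval)

  # --- stage 6: spatial models -------------------------------------------
  nitrate_fits <- NULL; presence_fit <- NULL
  mp <- props[props$size_m == config$model_size &
              props$buffer_type == config$model_type & !props$truncated, ]
  if (fit_models) {
    nitrate_fits <- nitrate_models(sites, props, size = config$model_size,
                                   type = config$model_type)
    covs <- with_seed(ss[["models"]], data.frame(
      site_id = mp$site_id,
      gradient = forest_agriculture_gradient(mp$forest, mp$pasture, mp$crop),
      altitude = sites$elevation_m[match(mp$site_id, sites$site_id)],
      # synthetic stand-ins for the hydrogeological/glaciation covariates
      dist_karst = stats::rlnorm(nrow(mp), log(2000), 0.8),
      dist_unconsolidated = stats::rlnorm(nrow(mp), log(500), 0.8),
      glaciation_lgm = stats::rbinom(nrow(mp), 1, 0.5)))
    presence_fit <- final_presence_model(sites, covs)
  }

  # --- stage 7: sampled vs random composition ----------------------------
  n_rand <- if (is.null(config$n_random)) nrow(sites) else config$n_random
  ext <- c(dem$xll + margin, dem$xll + dem$nx * dem$res - margin,
           dem$yll + margin, dem$yll + dem$ny * dem$res - margin)
  rand_sites <- generate_random_sites(ext, n_rand, seed = ss[["random_sites"]])
  rand_props <- landuse_proportions(rand_sites, dem, landuse,
                                    sizes = config$model_size,
                                    types = config$model_type)
  comparison <- compare_composition(mp, rand_props)

  manifest <- c(
    package_version = as.character(utils::packageVersion("stygoscale")),
    config_hash = config_hash(deparse(config[setdiff(names(config), "stage_seeds")])),
    master_seed = config$seed,
    stats::setNames(as.character(ss), paste0("seed_", names(ss))),
    n_sites = nrow(sites), peak_scale_m = peak$peak,
    zone_median_m = signif(zones$median_extent, 6))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sites_csv(sites, file.path(out_dir, "sites.csv"))
    utils::write.csv(proportions_long(props),
                     file.path(out_dir, "proportions.csv"), row.names = FALSE)
    utils::write.csv(scan, file.path(out_dir, "scan.csv"), row.names = FALSE)
    utils::write.csv(peak$profile, file.path(out_dir, "profile.csv"),
                     row.names = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "composition.csv"),
                     row.names = FALSE)
    zs <- c(sprintf("median_extent_m %.6g", zones$median_extent),
            sprintf("fraction_below_%g %.6g", config$zone_interval[1],
                    zones$fraction_below),
            sprintf("fold_low %.6g", zones$fold_range[1]),
            sprintf("fold_high %.6g", zones$fold_range[2]),
            sprintf("n_zones %d", zones$n_zones))
    writeLines(zs, file.path(out_dir, "zones.txt"))
    if (fit_models) {
      nt <- do.call(rbind, lapply(names(nitrate_fits), function(cl) {
        tab <- nitrate_fits[[cl]]$coefficients
        cbind(model = cl, tab)
      }))
      utils::write.csv(nt, file.path(out_dir, "nitrate_models.csv"),
                       row.names = FALSE)
      utils::write.csv(presence_fit$coefficients,
                       file.path(out_dir, "presence_model.csv"),
                       row.names = FALSE)
    }
    writeLines(paste(names(manifest), unname(manifest)),
               file.path(out_dir, "manifest.txt"))
  }

  list(sites = sites, proportions = props, scan = scan, peak = peak,
       zones = zones, nitrate_fits = nitrate_fits,
       presence_fit = presence_fit, comparison = comparison,
       manifest = manifest)
}
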