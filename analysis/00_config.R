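# Shared configuration for the analysis scripts 01-05.
#
# One default-condition study: a 15 x 15 km synthetic landscape (10 m cells),
# 300 drinking-water extraction sites, amphipod presence driven by forest
# cover within 600 m catchment buffers, Gamma-distributed nitrate driven by
# crop (+) and forest (-) cover, and log-normal protection-zone extents with
# a 327 m median. Every script regenerates what it needs deterministically
# from this configuration, so each can be run on its own (in order or not).

library(stygoscale)

MASTER_SEED <- 42L
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

CFG <- run_config(seed = MASTER_SEED)

# deterministic landscape + site table shared by all downstream scripts
build_study <- function(cfg = CFG) {
  ss <- cfg$stage_seeds
  lc <- cfg$landscape; lc$seed <- ss[["landscape"]]
  truth <- cfg$truth;  truth$seed <- ss[["responses"]]
  dem <- generate_dem(lc)
  landuse <- generate_landuse(lc)
  margin <- max(cfg$scan_sizes, cfg$model_size, truth$true_scale)
  sites <- place_sites(truth$n_sites, dem, truth$min_spacing,
                       seed = ss[["sites"]], edge_margin = margin)
  sites <- simulate_presence(sites, dem, landuse, truth)
  sites <- simulate_nitrate(sites, dem, landuse, truth)
  sites$zone_extent_m <- simulate_protection_zones(
    nrow(sites), truth$zone_median, truth$zone_log_sd, seed = ss[["zones"]])
  list(dem = dem, landuse = landuse, sites = sites, truth = truth,
       margin = margin)
}
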