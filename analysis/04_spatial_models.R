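# 04 -- Spatial mixed models with Matern covariance.
#
# (a) Nitrate: one spatial Gamma log-link regression per major land-use
#     class (forest, pasture, crop) on 600 m catchment-buffer coverage.
# (b) Occurrence: amphipod presence/absence against the forest-agriculture
#     gradient plus environmental covariates (altitude and synthetic
#     hydrogeology/glaciation stand-ins), with stepwise backward AIC
#     selection, reported in the usual mixed-model table layout.

source("analysis/00_config.R")

study <- build_study()
props <- landuse_proportions(study$sites, study$dem, study$landuse,
                             sizes = CFG$model_size, types = CFG$model_type)

cat("=== Nitrate vs land use (spatial Gamma, 600 m catchment buffers) ===\n")
nfits <- nitrate_models(study$sites, props, size = CFG$model_size,
                        type = CFG$model_type)
for (cl in names(nfits)) {
  co <- nfits[[cl]]$coefficients[2, ]
  cat(sprintf("%-8s slope per %% point: %+.4f (95%% CI %+.4f, %+.4f)\n",
              cl, co$estimate, co$ci_lo, co$ci_hi))
}
ntab <- do.call(rbind, lapply(names(nfits), function(cl)
  cbind(model = cl, nfits[[cl]]$coefficients)))
write.csv(ntab, file.path(RESULTS_DIR, "nitrate_models.csv"),
          row.names = FALSE)

cat("\n=== Amphipod occurrence (spatial binomial, backward AIC) ===\n")
mp <- props[!props$truncated, ]
covs <- with(mp, data.frame(
  site_id = site_id,
  gradient = forest_agriculture_gradient(forest, pasture, crop),
  altitude = study$sites$elevation_m[match(site_id, study$sites$site_id)]))
set.seed(CFG$stage_seeds[["models"]])
covs$dist_karst <- rlnorm(nrow(covs), log(2000), 0.8)
covs$dist_unconsolidated <- rlnorm(nrow(covs), log(500), 0.8)
covs$glaciation_lgm <- rbinom(nrow(covs), 1, 0.5)

fit <- final_presence_model(study$sites, covs)
print(fit)
cat("\nElimination trace:\n")
print(attr(fit, "trace"), row.names = FALSE)
if (fit$matern$lambda > 1e-3) {
  cat(sprintf("\nResidual spatial autocorrelation extends to ~%.0f m (corr < 0.05)\n",
              autocorrelation_range(fit)))
} else {
  cat("\nRandom-effect variance ~0: no residual spatial autocorrelation",
      "(the synthetic responses are conditionally independent given land use)\n")
}
write.csv(fit$coefficients, file.path(RESULTS_DIR, "presence_model.csv"),
          row.names = FALSE)
cat("Wrote nitrate_models.csv and presence_model.csv\n")
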