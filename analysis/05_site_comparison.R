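# 05 -- Land-use composition at sampled versus random sites, and the
#       ternary/gradient view of occurrence.
#
# Draws as many random reference sites as there are extraction sites,
# extracts their 600 m catchment-buffer composition, compares the cumulated
# class percentages with Wilcoxon tests (Bonferroni-adjusted over the four
# reported classes), and summarizes the forest-pasture-crop composition of
# presence vs absence sites in barycentric coordinates.

source("analysis/00_config.R")

study <- build_study()
props <- landuse_proportions(study$sites, study$dem, study$landuse,
                             sizes = CFG$model_size, types = CFG$model_type)
mp <- props[!props$truncated, ]

ext <- with(study$dem, c(xll + study$margin, xll + nx * res - study$margin,
                         yll + study$margin, yll + ny * res - study$margin))
rand <- generate_random_sites(ext, nrow(study$sites),
                              seed = CFG$stage_seeds[["random_sites"]])
rprops <- landuse_proportions(rand, study$dem, study$landuse,
                              sizes = CFG$model_size, types = CFG$model_type)

cmp <- compare_composition(mp, rprops)
write.csv(cmp, file.path(RESULTS_DIR, "composition.csv"), row.names = FALSE)
cat("Cumulated land-use percentages, sampled vs random sites (600 m catchment):\n")
print(cmp, row.names = FALSE, digits = 3)
cat("(synthetic sites are placed uniformly at random, so no composition\n",
    "difference is expected here; real extraction sites are biased toward\n",
    "forested locations)\n", sep = "")

m <- merge(study$sites, mp, by = "site_id")
tc <- ternary_coordinates(m$forest, m$pasture, m$crop)
for (g in c(1, 0)) {
  mu <- colMeans(tc[m$presence == g, ], na.rm = TRUE)
  cat(sprintf("%s sites: mean ternary composition forest %.2f, pasture %.2f, crop %.2f\n",
              if (g == 1) "Presence" else "Absence ",
              mu["forest"], mu["pasture"], mu["crop"]))
}
grad <- forest_agriculture_gradient(m$forest, m$pasture, m$crop)
cat(sprintf("Forest-agriculture gradient: presence mean %.1f, absence mean %.1f\n",
            mean(grad[m$presence == 1], na.rm = TRUE),
            mean(grad[m$presence == 0], na.rm = TRUE)))
cat("Wrote composition.csv\n")
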