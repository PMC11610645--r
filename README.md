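# stygoscale

Scale-of-effect analysis linking terrestrial land use to groundwater
quality and groundwater-amphipod occurrence.

Drinking-water extraction sites tap shallow aquifers beneath a mosaic of
forest, pasture, crop and built-up land. This package implements, as a
tested and reusable pipeline, the analysis chain used to ask two questions
about such systems: *does surface land use leave a signal in groundwater
nitrate and in the occurrence of obligate groundwater amphipods
(stygofauna), and at what spatial scale around the extraction site is that
signal strongest?* The answer matters for management because regulatory
groundwater protection zones usually end a few hundred meters from the
extraction point.

It is aimed at landscape/groundwater ecologists and at anyone wanting a
self-contained, ground-truthed testbed for scale-of-effect methodology.

## What it computes

- **Buffers** — for each site, land-use proportions within *round* buffers
  (radii 10 m–5 km) and *catchment* buffers: the subset of the round buffer
  at elevation ≥ site − 5 m, connected to the site allowing gaps up to
  50 m, approximating the surface drainage area (delineated from a DEM in
  compiled code, verified against a brute-force oracle).
- **Multi-scale scan** — one binomial GLM per (radius r, buffer type t,
  land-use class c): `logit P(presence) = α + β·coverage%`, scored by
  McFadden's pseudo R², `R²_McF = 1 − D/D₀`, with a 70%-subsampling SD.
  The *scale of effect* is `argmax_r mean_{t,c} R²_McF(r, t, c)`.
- **Spatial mixed models** — `g(E[y]) = Xβ + b(s)` with
  `b ~ N(0, λ·Matérn_ν,ρ)` over site coordinates,
  `corr(d) = 2^(1−ν)/Γ(ν)·(ρd)^ν·K_ν(ρd)`; Gamma log-link for nitrate per
  land-use class, binomial logit for occurrence on the forest–agriculture
  gradient `100·forest/(forest+pasture+crop)` plus covariates, with
  stepwise backward AIC. Fitted by Laplace-approximate maximum likelihood
  (authored here; see the methods vignette).
- **Zone contrast** — the scale-of-effect interval divided by the median
  protection-zone extent, plus Wilcoxon/Bonferroni composition comparisons
  of sampled versus random sites.
- **Synthetic generator** — Gaussian-random-field terrain and land-use
  mosaics, seeded site placement, and responses drawn from a known truth
  (presence driven by forest cover in a 600 m catchment buffer; Gamma
  nitrate driven by crop/forest; log-normal zone extents, median 327 m),
  so every stage is testable without any download.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic landscape (15 × 15 km at 10 m, 300 sites) and write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_buffers.R
Rscript analysis/03_scan.R
Rscript analysis/04_spatial_models.R
Rscript analysis/05_site_comparison.R
```

`03_scan.R` prints, for this configuration:

```
Mean pseudo R2 profile across 42 scan cells:
 size_m     mean_r2  sd_of_mean n_combos
    100 0.039965585 0.013004892        6
    200 0.057818297 0.015291777        6
    400 0.089329105 0.014767995        6
    600 0.091015568 0.014468305        6
    800 0.080594262 0.012421153        6
   1000 0.060556699 0.009999030        6
   2000 0.007340891 0.003221564        6

Scale of effect: 600 m (true simulated scale: 600 m)
Protection zones (n = 300): median extent 321 m
  66% of zones smaller than 400 m
  scale-of-effect interval 400-1000 m is 1.2- to 3.1-fold the median extent
```

The profile peaks at the true 600 m scale; slopes at the peak are positive
for forest and negative for pasture and crop; and the identified scale
interval exceeds the median protection-zone extent 1.2- to 3-fold.
`04_spatial_models.R` prints the spatial Gamma nitrate slopes (crop
positive, forest negative, per percentage point of coverage) and the
selected occurrence model in the usual mixed-model table layout (Est, SE,
t, 95% CI, p, then ν, ρ, λ and N_obs).

The same can be driven programmatically:

```r
library(stygoscale)
cfg <- run_config(seed = 42)          # landscape, truth, scan, model settings
res <- run_pipeline(cfg, out_dir = "results")
res$peak$peak                         # identified scale of effect (m)
res$zones                             # zone extents vs the 400-1000 m interval
res$presence_fit                      # selected spatial occurrence model
```

## Layout

```
R/            package implementation (generator, buffers, scan, spatial models,
              site statistics, pipeline orchestration)
src/          compiled buffer delineation (Rcpp)
analysis/     numbered narrative drivers over the package
scripts/      acceptance.R (see above)
tests/        testthat suite, including oracle-based and simulation tests
vignettes/    methods vignette: model definitions, parameter conventions,
              numerical choices, generator scope and limitations
```
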