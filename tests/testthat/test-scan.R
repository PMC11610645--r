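fixed_dataset <- function(n, seed, beta0 = -1, beta1 = 0.05) {
  set.seed(seed)
  x <- round(runif(n, 0, 100), 1)
  y <- rbinom(n, 1, plogis(beta0 + beta1 * x))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(x = x, y = y)
}

test_that("logistic fit matches an independent likelihood maximizer", {
  for (cfg in list(list(n = 20, seed = 1), list(n = 30, seed = 2),
                   list(n = 25, seed = 3))) {
    d <- fixed_dataset(cfg$n, cfg$seed)
    fit <- fit_binomial_glm(d$x, d$y)
    ora <- oracle_logistic(d$x, d$y)
    expect_lt(abs(fit$intercept - ora$beta[1]), 1e-6)
    expect_lt(abs(fit$slope - ora$beta[2]), 1e-6)
    expect_true(fit$converged)
    expect_lte(fit$deviance, fit$null_deviance + 1e-8)
  }
})

test_that("logistic fit guards: null effect, separation, degenerate input", {
  set.seed(10)
  x <- runif(500, 0, 100)
  y <- rbinom(500, 1, 0.4)  # independent of x
  fit <- fit_binomial_glm(x, y)
  expect_lt(abs(fit$slope / fit$slope_se), 3)

  xs <- runif(50, 0, 100)
  ys <- as.integer(xs > median(xs))  # complete separation
  sep <- fit_binomial_glm(xs, ys)
  expect_false(sep$converged)

  expect_error(fit_binomial_glm(x, rep(1, 500)), "degenerate")
  expect_error(fit_binomial_glm(x[1:5], y[1:5]), "at least 10")
})

test_that("McFadden pseudo R2: identities and the likelihood-ratio form", {
  expect_equal(mcfadden_pseudo_r2(50, 100), 0.5)
  expect_equal(mcfadden_pseudo_r2(100, 100), 0)
  expect_error(mcfadden_pseudo_r2(10, 0), "null_deviance")
  d <- fixed_dataset(30, 7)
  fit <- fit_binomial_glm(d$x, d$y)
  ora <- oracle_logistic(d$x, d$y)
  r2 <- mcfadden_pseudo_r2(fit$deviance, fit$null_deviance)
  expect_lt(abs(r2 - (1 - ora$loglik / ora$null_loglik)), 1e-8)
})

test_that("subsampling SD: degenerate zero, determinism, replicate stability", {
  set.seed(5)
  y <- rbinom(60, 1, 0.5)
  x_const <- rep(50, 60)
  expect_equal(as.numeric(subsample_r2_sd(x_const, y, reps = 20, seed = 1)), 0)

  d <- fixed_dataset(80, 12)
  s1 <- subsample_r2_sd(d$x, d$y, reps = 50, seed = 3)
  s2 <- subsample_r2_sd(d$x, d$y, reps = 50, seed = 3)
  expect_identical(s1, s2)

  big <- as.numeric(subsample_r2_sd(d$x, d$y, reps = 1000, seed = 4))
  small <- as.numeric(subsample_r2_sd(d$x, d$y, reps = 200, seed = 5))
  expect_lt(abs(big - small) / big, 0.25)

  expect_error(subsample_r2_sd(d$x, d$y, reps = 1), "reps")
  expect_error(subsample_r2_sd(d$x[1:12], d$y[1:12], frac = 0.7), "below 10")
})

test_that("scan covers the size x type x class grid and finds the signal", {
  fx <- small_landscape()
  sc <- scale_scan(fx$sites, fx$props, reps = 0)
  expect_equal(nrow(sc), 4 * 2 * 3)  # sizes x types x classes
  expect_true(all(sc$pseudo_r2 >= 0 & sc$pseudo_r2 <= 1))
  # the true driver: positive forest slope at the true 200 m scale
  at_true <- sc[sc$size_m == 200 & sc$class == "forest", ]
  expect_true(all(at_true$slope > 0))
  pk <- peak_scale(sc)
  expect_equal(pk$profile$n_combos, rep(6, 4))
  expect_equal(pk$profile$size_m[which.max(pk$profile$mean_r2)], pk$peak)
})

test_that("shuffling presence labels destroys the scan signal", {
  fx <- small_landscape()
  sc <- scale_scan(fx$sites, fx$props, reps = 0)
  peak_r2 <- max(sc$pseudo_r2[sc$class == "forest"])
  set.seed(31)
  beats <- 0L
  for (i in 1:20) {
    sh <- fx$sites
    sh$presence <- sample(sh$presence)
    sc_sh <- scale_scan(sh, fx$props, reps = 0)
    if (max(sc_sh$pseudo_r2) < peak_r2) beats <- beats + 1L
  }
  expect_gte(beats, 18L)
})

test_that("scan slope z-scores control type-I error under the null", {
  fx <- small_landscape()
  pr <- fx$props[fx$props$size_m == 200 & fx$props$buffer_type == "catchment", ]
  x <- 100 * pr$forest
  set.seed(55)
  hits <- 0L
  n_sim <- 200L
  for (i in seq_len(n_sim)) {
    y <- rbinom(length(x), 1, 0.35)
    f <- fit_binomial_glm(x, y)
    if (abs(f$slope / f$slope_se) > 1.96) hits <- hits + 1L
  }
  expect_gte(hits / n_sim, 0.02)
  expect_lte(hits / n_sim, 0.08)
})

test_that("peak profile: argmax, tie toward the smallest size", {
  cells <- data.frame(size_m = rep(c(400, 600, 800), each = 2),
                      buffer_type = "round", class = "forest",
                      pseudo_r2 = c(0.02, 0.02, 0.05, 0.05, 0.03, 0.03))
  expect_equal(peak_scale(cells)$peak, 600)
  flat <- transform(cells, pseudo_r2 = 0.04)
  expect_equal(peak_scale(flat)$peak, 400)
  expect_error(peak_scale(cells[cells$size_m == 400, ]), "2 sizes")
  expect_error(peak_scale(cells[0, ]), "empty")
})

test_that("zone summary reproduces the fold arithmetic and a sorting oracle", {
  zs <- zone_summary(327, c(400, 1000))
  expect_equal(round(zs$fold_range[1], 1), 1.2)
  expect_equal(round(zs$fold_range[2]), 3)
  expect_equal(zs$fold_range, c(400, 1000) / 327)

  same <- zone_summary(rep(250, 8), c(250, 250))
  expect_equal(same$fold_range, c(1, 1))

  set.seed(2)
  z <- rlnorm(1000, log(300), 0.5)
  zs2 <- zone_summary(z, c(400, 1000))
  srt <- sort(z)
  expect_equal(zs2$median_extent, (srt[500] + srt[501]) / 2)
  expect_equal(zs2$fraction_below, mean(z < 400))
  expect_error(zone_summary(numeric(0)), "no zone")
})

test_that("scan recovers a 200 m true scale on small landscapes", {
  hits <- 0L
  for (r in 1:6) {
    lc <- landscape_config(nx = 400, ny = 400, seed = 600 + r,
                           landuse_corr_length = 150)
    dem <- generate_dem(lc); lu <- generate_landuse(lc)
    tr <- truth_config(true_scale = 200, n_sites = 150, min_spacing = 100,
                       seed = 700 + r)
    sites <- place_sites(tr$n_sites, dem, tr$min_spacing, seed = 800 + r,
                         edge_margin = 400)
    sites <- simulate_presence(sites, dem, lu, tr)
    props <- landuse_proportions(sites, dem, lu, sizes = c(50, 100, 200, 400),
                                 types = c("round", "catchment"))
    pk <- peak_scale(scale_scan(sites, props, reps = 0))
    if (pk$peak %in% c(100, 200, 400)) hits <- hits + 1L
  }
  expect_gte(hits, 5L)  # true or adjacent size in nearly all replicates
})
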