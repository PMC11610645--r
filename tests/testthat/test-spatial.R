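# simulate one dataset from the spatial model
sim_spatial <- function(n, family, beta, lambda = 1, nu = 1, rho = 0.001,
                        shape = 4, seed = 1, extent = 15000) {
  set.seed(seed)
  coords <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  S <- matern_correlation(as.matrix(dist(coords)), nu, rho)
  dim(S) <- c(n, n); diag(S) <- 1
  b <- sqrt(lambda) * drop(crossprod(chol(S + diag(1e-8, n)), rnorm(n)))
  x <- runif(n, 0, 100)
  eta <- beta[1] + beta[2] * x + b
  y <- if (family == "binomial") rbinom(n, 1, plogis(eta))
       else rgamma(n, shape = shape, scale = exp(eta) / shape)
  list(X = cbind("(Intercept)" = 1, x = x), y = y, coords = coords)
}

test_that("Matern correlation: closed-form special cases and validity", {
  expect_equal(matern_correlation(0, 1.26, 0.00061), 1)
  # nu = 1/2 is exponential decay
  for (u in c(0.1, 1, 5))
    expect_lt(abs(matern_correlation(u / 0.002, 0.5, 0.002) - exp(-u)), 1e-10)
  # nu = 3/2 is (1 + u) exp(-u)
  expect_lt(abs(matern_correlation(1000, 1.5, 0.001) - 2 * exp(-1)), 1e-8)
  for (u in c(0.3, 2))
    expect_lt(abs(matern_correlation(u / 0.001, 1.5, 0.001) - (1 + u) * exp(-u)),
              1e-8)
  # strictly decreasing, and the induced matrix is positive definite
  d <- seq(0, 20000, by = 250)
  v <- matern_correlation(d, 1.26, 0.00061)
  expect_true(all(diff(v) < 0))
  set.seed(3)
  for (i in 1:5) {
    pts <- matrix(runif(2 * 40, 0, 10000), ncol = 2)
    M <- matern_correlation(as.matrix(dist(pts)), runif(1, 0.2, 3),
                            10^runif(1, -4, -2.5))
    dim(M) <- c(40, 40); diag(M) <- 1 + 1e-8
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  expect_error(matern_correlation(1, -1, 0.001), "nu")
})

test_that("autocorrelation range inverts the exponential case analytically", {
  expect_lt(abs(autocorrelation_range(list(nu = 0.5, rho = 0.001)) -
                (-log(0.05) / 0.001)), 0.01)
  expect_equal(autocorrelation_range(list(nu = 1, rho = 0.001), threshold = 1), 0)
  rng <- sapply(c(5e-4, 1e-3, 2e-3), function(r)
    autocorrelation_range(list(nu = 1, rho = r)))
  expect_true(all(diff(rng) < 0))
  expect_error(autocorrelation_range(list(nu = 1, rho = 1e-3), threshold = 0),
               "threshold")
})

test_that("vanishing random-effect variance recovers the plain GLM", {
  d <- sim_spatial(120, "binomial", c(-1, 0.03), lambda = 0, seed = 5)
  fit <- fit_spatial_glmm(d$X, d$y, d$coords, family = "binomial",
                          fix = list(lambda = 1e-8, nu = 1, rho = 0.001))
  g <- glm.fit(d$X, d$y, family = binomial())
  expect_lt(max(abs(fit$coefficients$estimate - g$coefficients)), 1e-4)
  # Laplace marginal log-likelihood converges to the exact GLM one
  ll_glm <- sum(dbinom(d$y, 1, g$fitted.values, log = TRUE))
  expect_lt(abs(fit$loglik - ll_glm) / abs(ll_glm), 1e-3)

  d2 <- sim_spatial(100, "gamma", c(3, 0.015), lambda = 0, seed = 6)
  fit2 <- fit_spatial_glmm(d2$X, d2$y, d2$coords, family = "gamma",
                           fix = list(lambda = 1e-8, nu = 1, rho = 0.001))
  g2 <- glm.fit(d2$X, d2$y, family = Gamma(link = "log"))
  expect_lt(max(abs(fit2$coefficients$estimate - g2$coefficients)), 1e-3)
})

test_that("constant gamma response pins the intercept at the link scale", {
  set.seed(8)
  coords <- cbind(runif(60, 0, 5000), runif(60, 0, 5000))
  x <- runif(60, 0, 100)
  y <- rep(12.5, 60)
  fit <- fit_spatial_glmm(cbind(1, x = x), y, coords, family = "gamma",
                          fix = list(lambda = 1e-6, nu = 1, rho = 0.001,
                                     shape = 10))
  expect_lt(abs(fit$coefficients$estimate[1] - log(12.5)), 1e-3)
  expect_lt(abs(fit$coefficients$estimate[2]), 1e-5)
})

test_that("fitting is deterministic and reports honest metadata", {
  d <- sim_spatial(100, "gamma", c(3, 0.01), seed = 11)
  f1 <- fit_spatial_glmm(d$X, d$y, d$coords, family = "gamma")
  f2 <- fit_spatial_glmm(d$X, d$y, d$coords, family = "gamma")
  expect_identical(f1$coefficients, f2$coefficients)
  expect_equal(f1$n_obs, 100)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * (2 + 3 + 1))
  expect_true(all(f1$coefficients$ci_lo < f1$coefficients$ci_hi))
  # duplicated coordinates are jittered, not fatal
  d$coords[2, ] <- d$coords[1, ]
  expect_message(fit_spatial_glmm(d$X, d$y, d$coords, family = "gamma"),
                 "jittered")
  expect_error(fit_spatial_glmm(cbind(d$X, d$X[, 2]), d$y, d$coords,
                                family = "gamma"), "singular")
})

test_that("spatial Gamma fit recovers known fixed effects", {
  est <- se <- numeric(6)
  for (r in 1:6) {
    d <- sim_spatial(150, "gamma", c(3, 0.015), lambda = 0.25, seed = 40 + r)
    f <- fit_spatial_glmm(d$X, d$y, d$coords, family = "gamma")
    est[r] <- f$coefficients$estimate[2]; se[r] <- f$coefficients$se[2]
  }
  expect_lt(abs(mean(est) - 0.015), 3 * sd(est) / sqrt(6) + 0.0015)
  expect_gte(mean(abs(est - 0.015) <= 1.96 * se), 0.5)
})

test_that("backward AIC selection drops noise and keeps signal", {
  set.seed(19)
  keep_signal <- 0L; drop_noise <- 0L
  reps <- 8L
  for (r in 1:reps) {
    d <- sim_spatial(150, "binomial", c(-1.5, 0.04), lambda = 0.5,
                     seed = 300 + r)
    noise <- runif(150, 0, 100)
    X <- cbind(d$X, noise = noise)
    full <- fit_spatial_glmm(X, d$y, d$coords, family = "binomial")
    sel <- stepwise_backward_aic(full)
    if ("x" %in% sel$coefficients$term) keep_signal <- keep_signal + 1L
    if (!"noise" %in% sel$coefficients$term) drop_noise <- drop_noise + 1L
  }
  expect_gte(keep_signal, reps - 1L)
  expect_gte(drop_noise, reps - 2L)
})

test_that("AIC of the selected model never exceeds the full model's", {
  d <- sim_spatial(150, "binomial", c(-0.5, 0), lambda = 0.5, seed = 91)
  X <- cbind(d$X, n1 = runif(150, 0, 100), n2 = runif(150, 0, 100))
  full <- fit_spatial_glmm(X, d$y, d$coords, family = "binomial")
  sel <- stepwise_backward_aic(full)
  expect_lte(sel$aic, full$aic)
  trace <- attr(sel, "trace")
  expect_equal(trace$aic[1], full$aic)
  # a single strong covariate is never dropped
  d2 <- sim_spatial(150, "binomial", c(-2, 0.06), lambda = 0.3, seed = 92)
  sel2 <- stepwise_backward_aic(
    fit_spatial_glmm(d2$X, d2$y, d2$coords, family = "binomial"))
  expect_true("x" %in% sel2$coefficients$term)
})

test_that("nitrate and presence model drivers run end-to-end on the fixture", {
  fx <- small_landscape()
  fits <- nitrate_models(fx$sites, fx$props, size = 200, type = "catchment")
  expect_named(fits, c("forest", "pasture", "crop"))
  expect_gt(fits$crop$coefficients$estimate[2], -0.01)   # crop slope ~ +0.015
  expect_lt(fits$forest$coefficients$estimate[2], 0.01)  # forest slope ~ -0.007
  expect_identical(
    fits$forest$coefficients,
    nitrate_models(fx$sites, fx$props, size = 200)$forest$coefficients)

  pr <- fx$props[fx$props$size_m == 200 & fx$props$buffer_type == "catchment", ]
  covs <- data.frame(site_id = pr$site_id,
                     gradient = forest_agriculture_gradient(pr$forest,
                                                            pr$pasture,
                                                            pr$crop))
  fit <- final_presence_model(fx$sites, covs)
  expect_true("gradient" %in% fit$coefficients$term)
  expect_gt(fit$coefficients$estimate[fit$coefficients$term == "gradient"], 0)
  expect_error(nitrate_models(fx$sites[1:10, ], fx$props, size = 200),
               "30 sites")
})
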