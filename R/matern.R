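#' Matern spatial correlation
#'
#' The standard two-parameter Matern correlation in the convention where the
#' inverse range `rho` multiplies distance:
#' `corr(d) = 2^(1-nu)/Gamma(nu) * (rho d)^nu * K_nu(rho d)` for `d > 0` and
#' `corr(0) = 1`. `nu = 0.5` reduces to exponential decay `exp(-rho d)`;
#' `nu = 1.5` to `(1 + rho d) exp(-rho d)`. A `rho` of 0.00061 per meter thus
#' implies a correlation range of several kilometers.
#'
#' Evaluated on the log scale with exponentially scaled Bessel functions so
#' large `rho * d` underflows gracefully to 0.
#'
#' @param d distance(s) in meters, `>= 0`.
#' @param nu smoothness, `> 0`.
#' @param rho inverse range (1/m), `> 0`.
#' @return correlation value(s) in \[0, 1\], strictly decreasing in `d`.
#' @export
matern_correlation <- function(d, nu, rho) {
  if (nu <= 0 || rho <= 0) stop("`nu` and `rho` must be > 0", call. = FALSE)
  if (any(d < 0)) stop("`d` must be >= 0", call. = FALSE)
  u <- rho * d
  out <- numeric(length(u))
  zero <- u < 1e-12
  out[zero] <- 1
  if (any(!zero)) {
    uu <- u[!zero]
    lc <- (1 - nu) * log(2) - lgamma(nu) + nu * log(uu) +
      log(besselK(uu, nu, expon.scaled = TRUE)) - uu
    out[!zero] <- pmin(exp(lc), 1)
  }
  out
}

#' Distance at which fitted spatial correlation falls below a threshold
#'
#' The smallest distance `d` with `matern_correlation(d, nu, rho) <=
#' threshold`, found by bisection. Used as the autocorrelation-range
#' diagnostic of a fitted spatial model.
#'
#' @param fit a `spatial_fit` (see [fit_spatial_glmm()]) or a list with
#'   elements `nu` and `rho`.
#' @param threshold correlation threshold in (0, 1\]; a threshold of 1 (or
#'   more) is met at distance 0.
#' @return distance in meters.
#' @export
autocorrelation_range <- function(fit, threshold = 0.05) {
  par <- if (inherits(fit, "spatial_fit")) fit$matern else fit
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (threshold >= 1) return(0)
  nu <- par$nu; rho <- par$rho
  hi <- 1 / rho
  it <- 0L
  while (matern_correlation(hi, nu, rho) > threshold) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 200L) stop("could not bracket the range", call. = FALSE)
  }
  lo <- 0
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (matern_correlation(mid, nu, rho) > threshold) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
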