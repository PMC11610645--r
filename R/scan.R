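#' Single-covariate binomial GLM (logit link)
#'
#' Maximum-likelihood logistic regression of presence/absence on one
#' coverage percentage, fitted by iteratively reweighted least squares.
#' Separation is flagged by fitted logits diverging beyond +/-15.
#'
#' @param x coverage percentage (0-100).
#' @param y presence/absence (0/1).
#' @param maxit IRLS iteration cap.
#' @return a list of class `gw_glm`: `intercept`, `slope` (per percentage
#'   point), `slope_se`, `deviance`, `null_deviance`, `converged`, `n`.
#' @export
fit_binomial_glm <- function(x, y, maxit = 100L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(y)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("degenerate response: only one class present", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = maxit))
  )
  coefs <- fit$coefficients
  eta <- drop(X %*% coefs)
  separated <- max(abs(eta)) > 15
  # unscaled covariance from the final IRLS weighted least-squares step
  p1 <- seq_len(fit$rank)
  covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  structure(list(intercept = unname(coefs[1]), slope = unname(coefs[2]),
                 slope_se = sqrt(covmat[2, 2]),
                 deviance = fit$deviance, null_deviance = fit$null.deviance,
                 converged = fit$converged && !separated, n = n),
            class = "gw_glm")
}

#' McFadden's pseudo R-squared
#'
#' `1 - deviance / null_deviance` for a likelihood-based model: 0 for the
#' intercept-only model, approaching 1 as the covariate explains the
#' response. Numerically negative values are clipped to 0 with a warning.
#'
#' @param deviance,null_deviance model and intercept-only deviances.
#' @return a fraction in \[0, 1\].
#' @export
mcfadden_pseudo_r2 <- function(deviance, null_deviance) {
  if (!is.finite(null_deviance) || null_deviance <= 0)
    stop("`null_deviance` must be > 0", call. = FALSE)
  r2 <- 1 - deviance / null_deviance
  if (r2 < 0) {
    if (r2 < -1e-8) warning("negative pseudo R-squared clipped to 0")
    r2 <- 0
  }
  min(r2, 1)
}

glm_r2_quick <- function(x, y, maxit = 100L) {
  X <- cbind(1, x)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-8, maxit = maxit)))
  mcfadden_pseudo_r2(fit$deviance, fit$null.deviance)
}

#' Subsampling SD of McFadden's pseudo R-squared
#'
#' Uncertainty of a scan cell's pseudo R-squared: refit the GLM on seeded
#' random subsamples of `frac` of the sites (drawn without replacement) and
#' take the SD (denominator n-1) of the pseudo R-squared values. Subsamples
#' with a single response class cannot be scored and are redrawn; the count
#' of redraws is attached as an attribute.
#'
#' @inheritParams fit_binomial_glm
#' @param frac subsample fraction (default 0.7).
#' @param reps number of subsamples (default 1000).
#' @param seed integer seed.
#' @return the SD, with attribute `redraws`.
#' @export
subsample_r2_sd <- function(x, y, frac = 0.7, reps = 1000L, seed = 1L) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(y)
  m <- floor(frac * n)
  if (m < 10) stop("subsample size below 10", call. = FALSE)
  if (reps < 2) stop("`reps` must be >= 2", call. = FALSE)
  with_seed(seed, {
    r2 <- numeric(reps)
    redraws <- 0L
    for (i in seq_len(reps)) {
      repeat {
        idx <- sample.int(n, m)
        if (length(unique(y[idx])) > 1) break
        redraws <- redraws + 1L
        if (redraws > 100L * reps)
          stop("could not draw two-class subsamples", call. = FALSE)
      }
      r2[i] <- glm_r2_quick(x[idx], y[idx])
    }
    structure(stats::sd(r2), redraws = redraws)
  })
}

#' Multi-scale land-use scan
#'
#' One binomial GLM per (buffer size, buffer type, land-use class):
#' presence/absence against the percentage coverage of the class within the
#' buffer, scored by slope and McFadden's pseudo R-squared, optionally with
#' the subsampling SD. Each cell draws its subsamples independently from a
#' seed derived from `seed` and the cell index.
#'
#' @param sites data frame with `site_id` and `presence`.
#' @param proportions wide proportions table from [landuse_proportions()].
#' @param sizes,types,classes scan grid; defaults to everything present in
#'   `proportions` and the three major classes.
#' @param reps subsampling replicates for the pseudo-R-squared SD; `0`
#'   disables subsampling (SD reported as `NA`).
#' @param frac subsample fraction.
#' @param seed integer master seed for the subsampling.
#' @return data frame of scan cells: `size_m`, `buffer_type`, `class`,
#'   `slope`, `slope_se`, `pseudo_r2`, `pseudo_r2_sd`, `n`, `converged`.
#' @export
scale_scan <- function(sites, proportions,
                       sizes = sort(unique(proportions$size_m)),
                       types = unique(proportions$buffer_type),
                       classes = c("forest", "pasture", "crop"),
                       reps = 0L, frac = 0.7, seed = 1L) {
  pres <- sites$presence[match(proportions$site_id, sites$site_id)]
  rows <- list(); k <- 0L
  for (type in types) for (size in sizes) for (cl in classes) {
    k <- k + 1L
    sel <- proportions$size_m == size & proportions$buffer_type == type &
           !proportions$truncated
    if (!any(sel)) {
      warning(sprintf("no data for size=%g type=%s; skipped", size, type))
      next
    }
    xv <- 100 * proportions[[cl]][sel]
    yv <- pres[sel]
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < 10 || length(unique(yv[ok])) < 2) {
      warning(sprintf("degenerate cell size=%g type=%s class=%s; skipped",
                      size, type, cl))
      next
    }
    fit <- fit_binomial_glm(xv[ok], yv[ok])
    r2 <- mcfadden_pseudo_r2(fit$deviance, fit$null_deviance)
    r2sd <- if (reps >= 2)
      as.numeric(subsample_r2_sd(xv[ok], yv[ok], frac = frac, reps = reps,
                                 seed = seed + k)) else NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(size_m = size, buffer_type = type, class = cl,
                 slope = fit$slope, slope_se = fit$slope_se, pseudo_r2 = r2,
                 pseudo_r2_sd = r2sd, n = fit$n, converged = fit$converged)
  }
  if (!length(rows)) stop("empty scan: no scoreable cells", call. = FALSE)
  do.call(rbind, rows)
}

#' Scale of effect: peak of the mean pseudo-R-squared profile
#'
#' Averages pseudo R-squared over land-use classes and buffer types at each
#' buffer size and returns the size maximizing the mean, with the full
#' profile (mean and SD of the mean across the class x type combinations).
#' Ties break toward the smallest size (conservative toward local effects).
#'
#' @param scan_cells output of [scale_scan()].
#' @return list with `peak` (size in m) and `profile` (data frame `size_m`,
#'   `mean_r2`, `sd_of_mean`, `n_combos`).
#' @export
peak_scale <- function(scan_cells) {
  if (is.null(scan_cells) || !nrow(scan_cells)) stop("empty scan", call. = FALSE)
  sizes <- sort(unique(scan_cells$size_m))
  if (length(sizes) < 2) stop("need at least 2 sizes", call. = FALSE)
  prof <- do.call(rbind, lapply(sizes, function(s) {
    v <- scan_cells$pseudo_r2[scan_cells$size_m == s]
    data.frame(size_m = s, mean_r2 = mean(v),
               sd_of_mean = stats::sd(v) / sqrt(length(v)), n_combos = length(v))
  }))
  peak <- prof$size_m[which.max(prof$mean_r2)]  # which.max takes the first max
  list(peak = peak, profile = prof)
}

#' Protection-zone extent summary
#'
#' Median zone extent, the fraction of zones smaller than the lower end of a
#' scale-of-effect interval, and how many fold the interval exceeds the
#' median extent.
#'
#' @param zone_extents positive extents in meters.
#' @param scale_interval `(low, high)` scale-of-effect interval in meters.
#' @return list of class `zone_summary`: `median_extent`, `fraction_below`,
#'   `fold_range`, `n_zones`.
#' @export
zone_summary <- function(zone_extents, scale_interval = c(400, 1000)) {
  zone_extents <- zone_extents[is.finite(zone_extents)]
  if (!length(zone_extents)) stop("no zone extents", call. = FALSE)
  if (any(zone_extents <= 0)) stop("zone extents must be positive", call. = FALSE)
  if (scale_interval[1] > scale_interval[2])
    stop("`scale_interval` must be ordered (low, high)", call. = FALSE)
  med <- stats::median(zone_extents)
  structure(list(median_extent = med,
                 fraction_below = mean(zone_extents < scale_interval[1]),
                 fold_range = scale_interval / med,
                 n_zones = length(zone_extents),
                 scale_interval = scale_interval),
            class = "zone_summary")
}

#' @export
print.zone_summary <- function(x, ...) {
  cat(sprintf("Protection zones (n = %d): median extent %.0f m\n",
              x$n_zones, x$median_extent))
  cat(sprintf("  %.0f%% of zones smaller than %g m\n",
              100 * x$fraction_below, x$scale_interval[1]))
  cat(sprintf("  scale-of-effect interval %g-%g m is %.1f- to %.1f-fold the median extent\n",
              x$scale_interval[1], x$scale_interval[2],
              x$fold_range[1], x$fold_range[2]))
  invisible(x)
}
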