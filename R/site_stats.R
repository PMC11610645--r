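#' Random reference sites, optionally stratified
#'
#' Uniform random site coordinates within a rectangular study region or a
#' set of named rectangular strata with target fractions (quotas by
#' largest-remainder rounding), emulating a random null expectation for the
#' land-use composition comparison while holding regional sampling density
#' constant.
#'
#' @param region either a [gw_raster()] (its extent is used) or a vector
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param n number of sites.
#' @param strata optional data frame with columns `name`, `xmin`, `xmax`,
#'   `ymin`, `ymax`, `fraction` (fractions summing to 1); `NULL` for a
#'   single stratum covering the region.
#' @param seed integer seed.
#' @return data frame `site_id`, `x`, `y`, `stratum`.
#' @export
generate_random_sites <- function(region, n, strata = NULL, seed = 1L) {
  ext <- if (inherits(region, "gw_raster"))
    c(region$xll, region$xll + region$nx * region$res,
      region$yll, region$yll + region$ny * region$res)
  else as.numeric(region)
  if (is.null(strata))
    strata <- data.frame(name = "all", xmin = ext[1], xmax = ext[2],
                         ymin = ext[3], ymax = ext[4], fraction = 1)
  if (abs(sum(strata$fraction) - 1) > 1e-9)
    stop("strata fractions must sum to 1", call. = FALSE)
  if (any(strata$xmax <= strata$xmin | strata$ymax <= strata$ymin))
    stop("empty stratum geometry", call. = FALSE)
  # largest-remainder quotas
  exact <- n * strata$fraction
  quota <- floor(exact)
  rem <- n - sum(quota)
  if (rem > 0) {
    add <- order(exact - quota, decreasing = TRUE)[seq_len(rem)]
    quota[add] <- quota[add] + 1
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
      k <- quota[i]
      if (k == 0) return(NULL)
      data.frame(x = stats::runif(k, strata$xmin[i], strata$xmax[i]),
                 y = stats::runif(k, strata$ymin[i], strata$ymax[i]),
                 stratum = strata$name[i])
    }))
    data.frame(site_id = seq_len(nrow(out)), out)
  })
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Location comparison of two samples: the exact null distribution when both
#' samples have at most `exact_max` observations and no ties, and the normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param a,b numeric samples.
#' @param exact_max sample-size bound for the exact path (default 12).
#' @return list with `statistic` (Mann-Whitney U of `a`), `p_value`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 12L) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (use_exact) "exact" else "normal")
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value, with `m` at least the number of tests.
#'
#' @param p p-values in \[0, 1\].
#' @param m number of tests (default `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p)) stop("`m` must be >= number of tests", call. = FALSE)
  pmin(1, m * p)
}

#' Significance labels
#'
#' The conventional star coding: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, `ns` otherwise.
#'
#' @param p p-values.
#' @return character vector of labels.
#' @export
significance_label <- function(p)
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))

#' Compare land-use composition of sampled versus random sites
#'
#' Per land-use class: the cumulated coverage percentage across each site
#' group (so each group's five classes sum to 100), a Wilcoxon rank-sum test
#' on the per-site proportions, and Bonferroni-adjusted p-values over the
#' `m` compared classes.
#'
#' @param sampled_props,random_props wide proportion tables from
#'   [landuse_proportions()] restricted to one (size, type), or any data
#'   frames with the class fraction columns.
#' @param classes classes tested (default the four named classes;
#'   "other" still appears in the cumulated percentages).
#' @param m number of Bonferroni tests (default `length(classes)`).
#' @return data frame: `class`, `random_pct`, `sampled_pct`, `p_raw`,
#'   `p_adj`, `signif`.
#' @export
compare_composition <- function(sampled_props, random_props,
                                classes = c("forest", "pasture", "crop",
                                            "construction"),
                                m = length(classes)) {
  all_cls <- landuse_classes()
  cum_pct <- function(df) {
    tot <- vapply(all_cls, function(cl) sum(df[[cl]]), 0)
    100 * tot / sum(tot)
  }
  rp <- cum_pct(random_props); sp <- cum_pct(sampled_props)
  p_raw <- vapply(classes, function(cl)
    wilcoxon_rank_sum(sampled_props[[cl]], random_props[[cl]])$p_value, 0)
  out <- data.frame(class = all_cls, random_pct = rp, sampled_pct = sp,
                    p_raw = NA_real_, p_adj = NA_real_, signif = NA_character_,
                    row.names = NULL)
  idx <- match(classes, all_cls)
  out$p_raw[idx] <- p_raw
  out$p_adj[idx] <- bonferroni(p_raw, m)
  out$signif[idx] <- significance_label(out$p_adj[idx])
  out
}

#' Forest-agriculture gradient
#'
#' Position of a site along the forest versus agriculture (pasture + crop)
#' axis: `100 * forest / (forest + pasture + crop)`, the vertical axis of
#' the ternary composition plot, treating the three major classes as 100%.
#'
#' @param forest,pasture,crop class fractions (or percentages; only ratios
#'   matter).
#' @return gradient value(s) in \[0, 100\]; `NA` (with a warning) where all
#'   three classes are zero, such sites being excluded downstream.
#' @export
forest_agriculture_gradient <- function(forest, pasture, crop) {
  tot <- forest + pasture + crop
  bad <- tot <= 0
  if (any(bad)) warning(sum(bad), " site(s) with no forest/pasture/crop cover: gradient undefined")
  ifelse(bad, NA_real_, 100 * forest / tot)
}

#' Barycentric (ternary) coordinates of the major land-use classes
#'
#' Normalizes the forest, pasture and crop fractions to sum to 1, the
#' coordinates of the ternary composition plot.
#'
#' @inheritParams forest_agriculture_gradient
#' @return data frame with columns `forest`, `pasture`, `crop` summing to 1
#'   per row (`NA` rows where all three are zero).
#' @export
ternary_coordinates <- function(forest, pasture, crop) {
  tot <- forest + pasture + crop
  bad <- tot <= 0
  if (any(bad)) warning(sum(bad), " site(s) with no forest/pasture/crop cover")
  tot[bad] <- NA_real_
  data.frame(forest = forest / tot, pasture = pasture / tot, crop = crop / tot)
}
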