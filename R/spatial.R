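#' @importFrom stats dbinom dgamma pnorm nlminb median dist
NULL

# Family helpers for the Laplace fit: expected-information working weights
# and log-likelihood. `shape` is the Gamma shape (ignored for binomial).
fam_mu <- function(family, eta)
  if (family == "binomial") stats::plogis(eta) else exp(eta)

fam_weights <- function(family, mu, shape) {
  if (family == "binomial") pmax(mu * (1 - mu), 1e-10)
  else rep(shape, length(mu))
}

fam_workz <- function(family, eta, mu, y) {
  if (family == "binomial") eta + (y - mu) / pmax(mu * (1 - mu), 1e-10)
  else eta + (y - mu) / mu
}

fam_loglik <- function(family, y, mu, shape) {
  if (family == "binomial") sum(stats::dbinom(y, 1, mu, log = TRUE))
  else sum(stats::dgamma(y, shape = shape, scale = mu / shape, log = TRUE))
}

# Penalized Fisher-scoring solve for (beta, b) given the correlation matrix
# lamS = lambda * Sigma. Returns the joint mode and the Laplace marginal
# log-likelihood  sum logf(y|eta) - b' Sigma^-1 b / (2 lambda)
#                 - 0.5 logdet(I + lambda W^1/2 Sigma W^1/2).
laplace_inner <- function(X, y, family, shape, lamS, cholS, lambda,
                          beta0 = NULL, b0 = NULL, maxit = 50L, tol = 1e-8) {
  n <- length(y); p <- ncol(X)
  beta <- if (is.null(beta0)) rep(0, p) else beta0
  b <- if (is.null(b0)) rep(0, n) else b0
  pen_old <- -Inf
  ok <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + b
    mu <- fam_mu(family, eta)
    w <- fam_weights(family, mu, shape)
    z <- fam_workz(family, eta, mu, y)
    V <- lamS + diag(1 / w, n)
    cv <- chol(V)
    Az <- backsolve(cv, forwardsolve(t(cv), z))
    AX <- backsolve(cv, forwardsolve(t(cv), X))
    beta_new <- solve(crossprod(X, AX), crossprod(X, Az))
    r <- z - drop(X %*% beta_new)
    b_new <- drop(lamS %*% backsolve(cv, forwardsolve(t(cv), r)))
    # step halving on the penalized log-likelihood
    step <- 1
    for (h in 1:10) {
      beta_try <- beta + step * (drop(beta_new) - beta)
      b_try <- b + step * (b_new - b)
      eta_t <- drop(X %*% beta_try) + b_try
      mu_t <- fam_mu(family, eta_t)
      sib <- forwardsolve(t(cholS), b_try)
      pen <- fam_loglik(family, y, mu_t, shape) - sum(sib^2) / (2 * lambda)
      if (is.finite(pen) && (pen >= pen_old - 1e-12 || h == 10)) break
      step <- step / 2
    }
    beta <- beta_try; b <- b_try
    if (is.finite(pen) && abs(pen - pen_old) < tol * (abs(pen) + 1)) { ok <- TRUE; break }
    pen_old <- pen
  }
  eta <- drop(X %*% beta) + b
  mu <- fam_mu(family, eta)
  w <- fam_weights(family, mu, shape)
  sw <- sqrt(w)
  M <- diag(n) + (sw %o% sw) * lamS
  ld <- 2 * sum(log(diag(chol(M))))
  sib <- forwardsolve(t(cholS), b)
  ll <- fam_loglik(family, y, mu, shape) - sum(sib^2) / (2 * lambda) - ld / 2
  list(beta = beta, b = b, loglik = ll, w = w, converged = ok)
}

#' Spatial GLMM with Matern covariance (Laplace-approximate ML)
#'
#' Fits `g(E[y]) = X beta + b(s)` where `b` is a zero-mean Gaussian random
#' effect over the site coordinates with covariance
#' `lambda * Matern(d; nu, rho)`. Supported families: binomial with logit
#' link and Gamma with log link (Gamma shape estimated jointly by ML).
#'
#' Estimation maximizes the Laplace-approximate marginal likelihood: an
#' inner penalized Fisher-scoring solve for `(beta, b)` given the covariance
#' parameters, and an outer quasi-Newton search over the log-transformed
#' covariance parameters (`nu` box-bounded to \[0.05, 10\]). For the
#' binomial-logit family expected and observed information coincide, so the
#' approximation is the exact Laplace one there. Wald standard errors come
#' from `(X' V^-1 X)^-1` with `V = W^-1 + lambda Sigma` at the optimum;
#' 95% CIs are `est +/- 1.96 se` and p-values are normal-based.
#'
#' Duplicated coordinates are deterministically jittered by 1 m (with a
#' message) so the correlation matrix stays positive definite.
#'
#' @param X fixed-effect design matrix (include the intercept column).
#' @param y response: 0/1 for binomial, positive for gamma.
#' @param coords n x 2 matrix of planar coordinates in meters.
#' @param family `"binomial"` or `"gamma"`.
#' @param fix optional named list fixing any of `lambda`, `nu`, `rho`,
#'   `shape` instead of estimating them.
#' @param start optional named list of starting values for the same.
#' @param control list: `outer_tol` (default 1e-6), `inner_tol` (1e-8),
#'   `outer_maxit` (200).
#' @return an object of class `spatial_fit`: `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `t`, `ci_lo`, `ci_hi`, `p`), `matern`
#'   (`nu`, `rho`, `lambda`), `shape` (gamma only), `loglik` (Laplace
#'   marginal), `aic`, `n_obs`, `converged`, plus the inputs needed to refit.
#'   AIC counts the fixed effects, the 3 covariance parameters and the Gamma
#'   shape where applicable.
#' @export
fit_spatial_glmm <- function(X, y, coords, family = c("binomial", "gamma"),
                             fix = list(), start = list(), control = list()) {
  family <- match.arg(family)
  X <- as.matrix(X); coords <- as.matrix(coords)
  n <- length(y)
  if (n < 30) stop("need at least 30 observations", call. = FALSE)
  if (nrow(X) != n || nrow(coords) != n) stop("dimension mismatch", call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design", call. = FALSE)
  ctl <- utils::modifyList(list(outer_tol = 1e-6, inner_tol = 1e-8,
                                outer_maxit = 200L), control)

  dup <- duplicated(coords)
  if (any(dup)) {
    k <- which(dup)
    ang <- 2.399963 * seq_along(k)  # golden-angle spiral, 1 m steps
    coords[k, 1] <- coords[k, 1] + cos(ang)
    coords[k, 2] <- coords[k, 2] + sin(ang)
    message(length(k), " duplicated coordinate(s) jittered by 1 m")
  }
  D <- as.matrix(stats::dist(coords))
  med_d <- stats::median(D[upper.tri(D)])

  # GLM starting values
  glm0 <- suppressWarnings(stats::glm.fit(
    X, y, family = if (family == "binomial") stats::binomial() else
      stats::Gamma(link = "log"),
    control = list(maxit = 100)))
  mu0 <- glm0$fitted.values
  shape_start <- if (family == "gamma")
    max(0.05, 1 / max(1e-3, mean(((y - mu0) / mu0)^2))) else NA

  defaults <- list(lambda = 1, nu = 1, rho = 2 / med_d, shape = shape_start)
  start <- utils::modifyList(defaults, start)
  parnames <- c("lambda", "nu", "rho", if (family == "gamma") "shape")
  free <- setdiff(parnames, names(fix))
  lower <- c(lambda = log(1e-10), nu = log(0.05), rho = log(1e-9), shape = log(0.01))
  upper <- c(lambda = log(1e4), nu = log(10), rho = log(10), shape = log(1e4))

  env <- new.env()
  env$beta <- glm0$coefficients
  env$b <- rep(0, n)
  env$cache_key <- NULL

  full_pars <- function(lp) {
    ps <- as.list(exp(lp))
    names(ps) <- free
    for (nm in names(fix)) ps[[nm]] <- fix[[nm]]
    ps
  }
  objective <- function(lp) {
    ps <- full_pars(lp)
    key <- paste(signif(c(ps$nu, ps$rho), 12), collapse = "_")
    if (!identical(env$cache_key, key)) {
      S <- matern_correlation(D, ps$nu, ps$rho)
      dim(S) <- dim(D)
      diag(S) <- 1 + 1e-8
      cs <- tryCatch(chol(S), error = function(e) NULL)
      if (is.null(cs)) return(1e10)
      env$S <- S; env$cholS <- cs; env$cache_key <- key
    }
    inner <- tryCatch(
      laplace_inner(X, y, family, ps$shape, ps$lambda * env$S, env$cholS,
                    ps$lambda, beta0 = env$beta, b0 = env$b,
                    tol = ctl$inner_tol),
      error = function(e) NULL)
    if (is.null(inner) || !is.finite(inner$loglik)) return(1e10)
    env$beta <- inner$beta; env$b <- inner$b
    -inner$loglik
  }

  lp0 <- if (length(free)) log(unlist(start[free])) else numeric(0)
  opt <- if (length(free)) {
    stats::nlminb(lp0, objective, lower = lower[free], upper = upper[free],
                  control = list(rel.tol = ctl$outer_tol,
                                 iter.max = ctl$outer_maxit))
  } else list(par = numeric(0), objective = objective(numeric(0)), convergence = 0)

  ps <- full_pars(opt$par)
  # final solve at the optimum
  S <- matern_correlation(D, ps$nu, ps$rho); dim(S) <- dim(D)
  diag(S) <- 1 + 1e-8
  cholS <- chol(S)
  inner <- laplace_inner(X, y, family, ps$shape, ps$lambda * S, cholS,
                         ps$lambda, beta0 = env$beta, b0 = env$b,
                         tol = ctl$inner_tol)
  V <- ps$lambda * S + diag(1 / inner$w, n)
  cv <- chol(V)
  AX <- backsolve(cv, forwardsolve(t(cv), X))
  covb <- solve(crossprod(X, AX))
  est <- inner$beta
  se <- sqrt(diag(covb))
  tv <- est / se
  coefs <- data.frame(term = colnames(X), estimate = est, se = se, t = tv,
                      ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                      p = 2 * stats::pnorm(-abs(tv)), row.names = NULL)
  npar <- ncol(X) + 3 + (family == "gamma")
  structure(list(family = family, coefficients = coefs,
                 matern = list(nu = ps$nu, rho = ps$rho, lambda = ps$lambda),
                 shape = if (family == "gamma") ps$shape else NULL,
                 loglik = inner$loglik, aic = -2 * inner$loglik + 2 * npar,
                 n_obs = n,
                 converged = inner$converged &&
                   (!length(free) || opt$convergence %in% c(0L, 1L)),
                 b = inner$b, X = X, y = y, coords = coords,
                 fix = fix, control = control),
            class = "spatial_fit")
}

#' @export
print.spatial_fit <- function(x, ...) {
  cat(sprintf("Spatial mixed model (%s family, Matern covariance), Laplace-approximate ML\n",
              x$family))
  cat("\nPredictors\n")
  tab <- x$coefficients
  print(data.frame(Est = signif(tab$estimate, 3), SE = signif(tab$se, 3),
                   t = signif(tab$t, 3),
                   `95% CI` = sprintf("%.3g, %.3g", tab$ci_lo, tab$ci_hi),
                   `p value` = format.pval(tab$p, digits = 2),
                   row.names = tab$term, check.names = FALSE))
  cat("\nRandom effect\n")
  cat(sprintf("  nu, rho          %.3g, %.3g\n", x$matern$nu, x$matern$rho))
  cat(sprintf("  var. lambda      %.3g\n", x$matern$lambda))
  if (!is.null(x$shape)) cat(sprintf("  Gamma shape      %.3g\n", x$shape))
  cat(sprintf("  N obs            %d\n", x$n_obs))
  cat(sprintf("  logLik %.2f  AIC %.2f%s\n", x$loglik, x$aic,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

refit_spatial <- function(fit, keep_terms) {
  fit_spatial_glmm(fit$X[, keep_terms, drop = FALSE], fit$y, fit$coords,
                   family = fit$family, fix = fit$fix, control = fit$control)
}

#' Stepwise backward model selection by AIC
#'
#' Repeatedly removes the single candidate term whose removal most lowers
#' the AIC of the refitted spatial model, until no removal lowers it. The
#' intercept and the spatial random effect are never dropped; covariance
#' parameters are re-estimated at every candidate refit. A refit that fails
#' to converge leaves its term in the model (logged in the trace).
#'
#' @param fit a converged `spatial_fit` of the full model.
#' @param candidate_terms character vector of droppable design columns;
#'   defaults to every non-intercept column.
#' @return the selected `spatial_fit`, with attribute `trace`: a data frame
#'   of the elimination path (step, dropped term, AIC).
#' @export
stepwise_backward_aic <- function(fit, candidate_terms = NULL) {
  stopifnot(inherits(fit, "spatial_fit"))
  if (is.null(candidate_terms))
    candidate_terms <- setdiff(colnames(fit$X), "(Intercept)")
  trace <- data.frame(step = 0L, dropped = "<full model>", aic = fit$aic,
                      stringsAsFactors = FALSE)
  current <- fit
  cand <- intersect(candidate_terms, colnames(current$X))
  step <- 0L
  while (length(cand)) {
    aics <- rep(NA_real_, length(cand))
    refits <- vector("list", length(cand))
    for (i in seq_along(cand)) {
      keep <- setdiff(colnames(current$X), cand[i])
      rf <- tryCatch(refit_spatial(current, keep), error = function(e) NULL)
      if (!is.null(rf) && rf$converged) {
        refits[[i]] <- rf
        aics[i] <- rf$aic
      }
    }
    if (all(is.na(aics)) || min(aics, na.rm = TRUE) >= current$aic) break
    i <- which.min(aics)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, dropped = cand[i],
                                     aic = aics[i]))
    current <- refits[[i]]
    cand <- intersect(cand, colnames(current$X))
  }
  attr(current, "trace") <- trace
  current
}

#' Nitrate versus land use: three spatial Gamma regressions
#'
#' One spatial Gamma log-link model per major land-use class (forest,
#' pasture, crop), each with the class's coverage percentage within the
#' chosen buffer as the single fixed effect. Slopes are per percentage
#' point of coverage.
#'
#' @param sites data frame with `site_id`, `x`, `y` and `nitrate_mg_l`.
#' @param proportions wide table from [landuse_proportions()].
#' @param size,type buffer size (m) and type at which proportions are taken
#'   (default: 600 m catchment buffers).
#' @param classes classes to model.
#' @return named list of `spatial_fit` objects.
#' @export
nitrate_models <- function(sites, proportions, size = 600, type = "catchment",
                           classes = c("forest", "pasture", "crop")) {
  pr <- proportions[proportions$size_m == size &
                    proportions$buffer_type == type & !proportions$truncated, ]
  m <- merge(sites, pr, by = "site_id")
  m <- m[is.finite(m$nitrate_mg_l) & m$nitrate_mg_l > 0, ]
  if (nrow(m) < 30)
    stop("fewer than 30 sites with nitrate measurements; collect more sites ",
         "or relax the buffer truncation filter", call. = FALSE)
  out <- list()
  for (cl in classes) {
    X <- cbind("(Intercept)" = 1, 100 * m[[cl]])
    colnames(X)[2] <- paste0(cl, "_pct")
    out[[cl]] <- fit_spatial_glmm(X, m$nitrate_mg_l, cbind(m$x, m$y),
                                  family = "gamma")
  }
  out
}

#' Final presence/absence model with covariates and model selection
#'
#' The headline occurrence model: amphipod presence/absence against the
#' forest-agriculture gradient plus environmental covariates, as a spatial
#' binomial-logit mixed model, followed by stepwise backward AIC selection.
#'
#' @param sites data frame with `site_id`, `x`, `y`, `presence`.
#' @param covariates data frame with `site_id`, `gradient` (0-100) and any
#'   further covariate columns.
#' @param select apply [stepwise_backward_aic()] to the full fit.
#' @return the selected `spatial_fit` (with elimination `trace` attribute
#'   when `select = TRUE`).
#' @export
final_presence_model <- function(sites, covariates, select = TRUE) {
  m <- merge(sites, covariates, by = "site_id")
  terms <- setdiff(names(covariates), "site_id")
  ok <- stats::complete.cases(m[c("presence", terms)]) & is.finite(m$presence)
  if (any(!ok))
    message(sum(!ok), " site(s) with missing response/covariates excluded")
  m <- m[ok, ]
  X <- cbind("(Intercept)" = 1, as.matrix(m[terms]))
  fit <- fit_spatial_glmm(X, m$presence, cbind(m$x, m$y), family = "binomial")
  if (select) fit <- stepwise_backward_aic(fit)
  fit
}
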