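# Independent brute-force oracles used to validate the fast implementations.

# Connected-component catchment oracle: enumerate round-buffer cells whose
# elevation passes the drop criterion, link any two qualifying cells whose
# centers are within gap_m, and keep the component containing the site cell
# (which is always included). Grown by plain R BFS over an explicit distance
# graph -- independent of the package's region-growing code path.
oracle_catchment <- function(dem, sx, sy, size, drop_m = 5, gap_m = 50) {
  res <- dem$res; ny <- dem$ny; nx <- dem$nx
  cc <- expand.grid(row = seq_len(ny), col = seq_len(nx))
  cx <- dem$xll + (cc$col - 0.5) * res
  cy <- dem$yll + (ny - cc$row + 0.5) * res
  selev <- raster_value_at(dem, sx, sy)
  in_round <- (cx - sx)^2 + (cy - sy)^2 <= size^2
  qual <- in_round & (dem$values[cbind(cc$row, cc$col)] >= selev - drop_m)
  scol <- floor((sx - dem$xll) / res) + 1
  srow <- ny - floor((sy - dem$yll) / res)
  sidx <- which(cc$row == srow & cc$col == scol)
  qual[sidx] <- TRUE
  qi <- which(qual)
  d2 <- outer(cx[qi], cx[qi], "-")^2 + outer(cy[qi], cy[qi], "-")^2
  adj <- d2 <= gap_m^2 + 1e-9
  member <- rep(FALSE, length(qi))
  member[match(sidx, qi)] <- TRUE
  repeat {
    grown <- member | (colSums(adj[member, , drop = FALSE]) > 0 & qual[qi])
    if (all(grown == member)) break
    member <- grown
  }
  cells <- cbind(cc$row[qi[member]], cc$col[qi[member]])
  cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
}

# Direct Bernoulli log-likelihood maximizer for logistic regression on one
# covariate: Newton iterations on the analytic score/Hessian, started from
# zero -- independent of glm.fit's IRLS bookkeeping.
oracle_logistic <- function(x, y, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- crossprod(X, y - mu)
    H <- crossprod(X * (mu * (1 - mu)), X)
    step <- solve(H, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  list(beta = beta,
       loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)),
       null_loglik = {
         p0 <- mean(y)
         sum(y * log(p0) + (1 - y) * log(1 - p0))
       })
}

# Exhaustive-enumeration two-sided rank-sum p-value (tie-free samples):
# enumerate every assignment of the pooled ranks to group A and count rank
# sums at least as extreme as the observed one.
oracle_wilcoxon_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  sets <- utils::combn(na + nb, na)
  all_r <- rank(seq_len(na + nb))
  w_all <- apply(sets, 2, function(ix) sum(all_r[ix]))
  mu <- na * (na + nb + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Small shared landscape fixture with a true forest effect at 200 m
# (kept small so response-simulation tests stay fast). Cached per session.
.fixture_env <- new.env()
small_landscape <- function() {
  if (is.null(.fixture_env$small)) {
    lc <- landscape_config(nx = 400, ny = 400, seed = 11,
                           landuse_corr_length = 150)
    dem <- generate_dem(lc)
    lu <- generate_landuse(lc)
    tr <- truth_config(true_scale = 200, n_sites = 150, min_spacing = 100,
                       beta_forest = 0.04, seed = 21)
    sites <- place_sites(tr$n_sites, dem, tr$min_spacing, seed = 31,
                         edge_margin = 400)
    sites <- simulate_presence(sites, dem, lu, tr)
    sites <- simulate_nitrate(sites, dem, lu, tr)
    props <- landuse_proportions(sites, dem, lu, sizes = c(50, 100, 200, 400),
                                 types = c("round", "catchment"))
    .fixture_env$small <- list(lc = lc, dem = dem, lu = lu, truth = tr,
                               sites = sites, props = props)
  }
  .fixture_env$small
}
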