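flat_dem <- function(n = 50, res = 10, value = 500)
  gw_raster(matrix(value, n, n), res = res)

test_that("round buffers match brute-force center-in-circle membership", {
  dem <- flat_dem(50)
  # site at a cell center
  site <- data.frame(site_id = 1, x = 255, y = 255)
  # degenerate radius: only the site's own cell
  tiny <- make_round_buffer(site, 4, dem)
  expect_equal(tiny$n_cells, 1L)
  expect_equal(unname(tiny$cells[1, ]), unname(c(cell_index(dem, 255, 255)$row,
                                                 cell_index(dem, 255, 255)$col)))
  # 50 m radius vs exhaustive distance test over all cells
  buf <- make_round_buffer(site, 50, dem)
  grid <- expand.grid(row = 1:50, col = 1:50)
  cx <- (grid$col - 0.5) * 10; cy <- (50 - grid$row + 0.5) * 10
  inside <- (cx - 255)^2 + (cy - 255)^2 <= 50^2
  expect_equal(buf$n_cells, sum(inside))
  got <- buf$cells[order(buf$cells[, 1], buf$cells[, 2]), ]
  want <- as.matrix(grid[inside, c("row", "col")])
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(unname(got), unname(want))
})

test_that("discretized area approaches pi r^2 for radii >= 20 cells", {
  dem <- flat_dem(500)
  site <- data.frame(site_id = 1, x = 2500, y = 2500)
  for (size in c(200, 400, 1000)) {
    buf <- make_round_buffer(site, size, dem)
    expect_lt(abs(buf$area / (pi * size^2) - 1), 0.05)
  }
})

test_that("edge truncation is flagged and left to the caller", {
  dem <- flat_dem(50)
  near_edge <- data.frame(site_id = 1, x = 30, y = 250)
  expect_true(make_round_buffer(near_edge, 100, dem)$truncated)
  expect_false(make_round_buffer(near_edge, 20, dem)$truncated)
})

test_that("catchment equals round buffer on flat and uphill-everywhere DEMs", {
  site <- data.frame(site_id = 1, x = 255, y = 255)
  flat <- flat_dem(50)
  r <- make_round_buffer(site, 120, flat)
  c1 <- delineate_catchment_buffer(site, 120, flat)
  expect_equal(c1$cells[order(c1$cells[, 1], c1$cells[, 2]), ],
               r$cells[order(r$cells[, 1], r$cells[, 2]), ])
  # elevation strictly increasing with distance from the site
  grid <- expand.grid(row = 1:50, col = 1:50)
  cx <- (grid$col - 0.5) * 10; cy <- (50 - grid$row + 0.5) * 10
  bowl <- gw_raster(matrix(sqrt((cx - 255)^2 + (cy - 255)^2) / 10, 50, 50),
                    res = 10)
  c2 <- delineate_catchment_buffer(site, 120, bowl)
  expect_equal(c2$n_cells, r$n_cells)
})

test_that("a qualifying hill across a wide deep valley is discarded, a narrow valley is bridged", {
  # site on a hill at x ~ 150 m; valley 10 m deep; second hill beyond it
  n <- 60; res <- 10
  cx <- (col(matrix(0, n, n)) - 0.5) * res
  valley_wide <- ifelse(cx < 200, 500, ifelse(cx < 300, 490, 505))  # 100 m gap
  valley_narrow <- ifelse(cx < 200, 500, ifelse(cx < 240, 490, 505)) # 40 m gap
  site <- data.frame(site_id = 1, x = 150, y = 300)
  wide <- delineate_catchment_buffer(site, 250, gw_raster(valley_wide, res = res))
  narrow <- delineate_catchment_buffer(site, 250, gw_raster(valley_narrow, res = res))
  wide_cols <- unique(wide$cells[, 2])
  narrow_cols <- unique(narrow$cells[, 2])
  expect_true(all((wide_cols - 0.5) * res < 300))   # far hill excluded
  expect_true(any((narrow_cols - 0.5) * res > 240)) # far hill bridged
})

test_that("catchment delineation matches the graph-component oracle on random terrain", {
  set.seed(42)
  for (i in 1:10) {
    lc <- landscape_config(nx = 50, ny = 50, dem_amplitude = 8,
                           dem_corr_length = 120, seed = 1000 + i)
    dem <- generate_dem(lc)
    site <- data.frame(site_id = 1, x = runif(1, 200, 300), y = runif(1, 200, 300))
    gap <- sample(c(30, 50, 80), 1)
    drop <- sample(c(2, 5), 1)
    got <- delineate_catchment_buffer(site, 180, dem, drop_m = drop, gap_m = gap)
    want <- oracle_catchment(dem, site$x, site$y, 180, drop_m = drop, gap_m = gap)
    got_cells <- got$cells[order(got$cells[, 1], got$cells[, 2]), , drop = FALSE]
    expect_equal(unname(got_cells), unname(want))
  }
})

test_that("buffer nesting and limit-parameter properties hold", {
  lc <- landscape_config(nx = 80, ny = 80, dem_amplitude = 10,
                         dem_corr_length = 150, seed = 7)
  dem <- generate_dem(lc)
  site <- data.frame(site_id = 1, x = 405, y = 405)
  key <- function(b) paste(b$cells[, 1], b$cells[, 2])
  site_cell <- cell_index(dem, 405, 405)
  for (type in c("round", "catchment")) {
    prev <- NULL
    for (size in c(50, 150, 300)) {
      b <- if (type == "round") make_round_buffer(site, size, dem)
           else delineate_catchment_buffer(site, size, dem)
      expect_true(paste(site_cell$row, site_cell$col) %in% key(b))
      if (!is.null(prev)) expect_true(all(prev %in% key(b)))
      prev <- key(b)
    }
  }
  r <- make_round_buffer(site, 300, dem)
  ct <- delineate_catchment_buffer(site, 300, dem)
  expect_true(all(key(ct) %in% key(r)))
  # drop = Inf recovers the round buffer; gap = Inf keeps every qualifying cell
  expect_setequal(key(delineate_catchment_buffer(site, 300, dem, drop_m = Inf)),
                  key(r))
  all_qual <- delineate_catchment_buffer(site, 300, dem, gap_m = Inf)
  strict <- delineate_catchment_buffer(site, 300, dem)
  expect_true(all(key(strict) %in% key(all_qual)))
  selev <- raster_value_at(dem, 405, 405)
  qual_n <- sum(dem$values[r$cells] >= selev - 5)
  expect_gte(all_qual$n_cells, qual_n)  # qualifying cells plus the site cell
})

test_that("proportion extraction equals an exhaustive per-cell tally", {
  dem <- flat_dem(50)
  lu_mat <- matrix(sample(1:5, 2500, TRUE, prob = c(0.4, 0.2, 0.2, 0.1, 0.1)),
                   50, 50)
  lu <- gw_raster(lu_mat, res = 10)
  site <- data.frame(site_id = 1, x = 255, y = 255)
  reg <- make_round_buffer(site, 100, dem)
  got <- extract_proportions(reg, lu)
  want <- sapply(1:5, function(k) mean(lu_mat[reg$cells] == k))
  expect_equal(unname(got), want)
  expect_equal(sum(got), 1)
  # uniform raster: single class gets everything
  ones <- gw_raster(matrix(1L, 50, 50), res = 10)
  expect_equal(unname(extract_proportions(reg, ones)),
               c(1, 0, 0, 0, 0))
  # unmapped code errors
  lu_bad <- gw_raster(matrix(7L, 50, 50), res = 10)
  expect_error(extract_proportions(reg, lu_bad), "unmapped")
})

test_that("reclassification maps raw codes totally or fails loudly", {
  raw <- gw_raster(matrix(c(1L, 2L, 2L, 1L), 2, 2), res = 10)
  ident <- reclassify(raw, c(`1` = "forest", `2` = "pasture"))
  expect_equal(ident$values, raw$values)
  merged <- reclassify(raw, c(`1` = "forest", `2` = "forest"))
  expect_true(all(merged$values == 1))
  expect_error(reclassify(raw, c(`1` = "forest")), "unmapped input code")
  expect_error(reclassify(raw, c(`1` = "forest", `2` = "lake")), "class labels")
})

test_that("bulk proportion extraction agrees with the single-site path", {
  fx <- small_landscape()
  pr <- fx$props
  expect_true(all(abs(rowSums(pr[landuse_classes()]) - 1) < 1e-9))
  idx <- which(pr$size_m == 200 & pr$buffer_type == "catchment")[c(3, 50, 101)]
  for (i in idx) {
    site <- fx$sites[fx$sites$site_id == pr$site_id[i], ]
    reg <- delineate_catchment_buffer(site, 200, fx$dem)
    single <- extract_proportions(reg, fx$lu)
    expect_equal(unlist(pr[i, landuse_classes()]), single)
    expect_equal(pr$n_cells[i], reg$n_cells)
  }
  # long format round-trips totals
  long <- proportions_long(pr)
  expect_equal(nrow(long), 5 * nrow(pr))
  expect_equal(sum(long$proportion), nrow(pr))
})
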