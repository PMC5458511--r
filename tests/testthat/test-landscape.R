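# Landscape tests drive build_landscape directly from coefficient/count
# tables, which gives exact control over bin geometry and occupancy.

test_that("Boltzmann energies follow -ln(count ratios) exactly without smoothing", {
  coords <- rbind(c(-1, 0), c(1, 0))
  # equal occupancy: both bins at zero energy
  l <- build_landscape(coords, c(100, 100), bins = c(8, 8),
                       smoothing_sigma = 0)
  e <- l$energy[is.finite(l$energy)]
  expect_equal(sort(e), c(0, 0))
  # 1000 vs 135: -ln(135/1000) = 2.0025
  l2 <- build_landscape(coords, c(1000, 135), bins = c(8, 8),
                        smoothing_sigma = 0)
  e2 <- l2$energy[is.finite(l2$energy)]
  expect_equal(sort(e2), c(0, -log(135 / 1000)), tolerance = 1e-12)
  expect_equal(max(e2), 2.0025, tolerance = 0.01)
})

test_that("occupancy is conserved and a single class gives one zero-energy bin", {
  l <- build_landscape(rbind(c(0.3, -0.2)), counts = 5000, bins = c(16, 16),
                       smoothing_sigma = 0)
  expect_equal(sum(l$occupancy), 5000)
  expect_equal(sum(is.finite(l$energy)), 1)
  expect_equal(min(l$energy, na.rm = TRUE), 0)
})

test_that("energies are invariant to scaling all counts", {
  set.seed(5)
  coords <- matrix(stats::rnorm(40), 20, 2)
  counts <- stats::rpois(20, 50) + 1
  l1 <- build_landscape(coords, counts, bins = c(10, 10), smoothing_sigma = 0)
  l2 <- build_landscape(coords, counts * 7, bins = c(10, 10),
                        smoothing_sigma = 0)
  expect_equal(l1$energy, l2$energy, tolerance = 1e-12)
})

test_that("empty bins are NaN unless capped", {
  coords <- rbind(c(-1, -1), c(1, 1))
  l <- build_landscape(coords, c(10, 40), bins = c(6, 6), smoothing_sigma = 0)
  expect_true(any(is.nan(l$energy)))
  lc <- build_landscape(coords, c(10, 40), bins = c(6, 6), smoothing_sigma = 0,
                        cap_empty = TRUE)
  expect_false(any(is.nan(lc$energy)))
  expect_equal(max(lc$energy), -log(10 / 40) + 1)
})

# a deterministic double-well occupancy: points on a 1D line through 2D
# space, counts = exp(-E) with two wells at 0 and a 3 kT saddle between
double_well_grid <- function(barrier = 3) {
  # integer abscissae with unit spacing so that the 44-bin axis (5% margin)
  # puts every point in its own bin: binning is exactly under control
  x <- 0:40
  e <- barrier * exp(-((x - 20) / 5)^2) + 4 * pmax(0, (abs(x - 20) - 15) / 5)^2
  counts <- round(1e6 * exp(-e))
  list(coords = cbind(x, 0.005 * (x - 20)^2), counts = counts, e = e, x = x)
}

test_that("minima and the minimax-path barrier are found on a double well", {
  dw <- double_well_grid(3)
  l <- build_landscape(dw$coords, dw$counts, bins = c(44, 8),
                       smoothing_sigma = 0)
  br <- find_minima_and_barrier(l)
  expect_gte(nrow(br$minima), 2)
  expect_lt(max(abs(br$minima$energy[1:2])), 1e-6)
  expect_lt(abs(br$barrier_height - 3), 0.01)
  expect_false(br$disconnected)
  # the reported path actually crosses the saddle
  expect_equal(max(br$path$energy), br$barrier_level, tolerance = 1e-9)
})

test_that("a flat landscape has zero barrier", {
  coords <- as.matrix(expand.grid(x = 1:5, y = 1:5))
  l <- build_landscape(coords, rep(100, 25), bins = c(5, 5),
                       smoothing_sigma = 0)
  br <- find_minima_and_barrier(l)
  expect_equal(br$barrier_height, 0)
})

test_that("disconnected minima give an infinite barrier flag", {
  coords <- rbind(c(-2, -2), c(2, 2))   # far corners, NaN in between
  l <- build_landscape(coords, c(50, 50), bins = c(9, 9), smoothing_sigma = 0)
  br <- find_minima_and_barrier(l)
  expect_true(br$disconnected)
  expect_equal(br$barrier_height, Inf)
})

test_that("doubling the smoothing never deepens the barrier", {
  dw <- double_well_grid(3)
  heights <- vapply(c(1, 2, 4), function(sg) {
    l <- build_landscape(dw$coords, dw$counts, bins = c(44, 8),
                         smoothing_sigma = sg)
    find_minima_and_barrier(l)$barrier_height
  }, numeric(1))
  expect_true(all(diff(heights) <= 1e-9))
})

test_that("landscape comparison reports differences and area contraction", {
  set.seed(8)
  # harmonic occupancies of two stiffnesses on identical binning
  x <- seq(-25, 25, length.out = 41)
  coords <- cbind(x, 0 * x)
  mk <- function(kappa) round(1e6 * exp(-kappa / 2 * x^2)) |>
    build_landscape(coefficients = coords, counts = _, bins = c(32, 4),
                    smoothing_sigma = 0)
  a <- mk(0.02); b <- mk(0.08)
  self <- compare_landscapes(a, a)
  expect_equal(self$summary$occupied_area_ratio, 1)
  expect_equal(max(abs(self$difference), na.rm = TRUE), 0)
  ab <- compare_landscapes(a, b)
  expect_lt(ab$summary$occupied_area_ratio, 1)
  l_other <- build_landscape(coords, rep(10, 41), bins = c(16, 4),
                             smoothing_sigma = 0)
  expect_error(compare_landscapes(a, l_other), "binning|rebin")
})

test_that("tidy, glance and autoplot work on a landscape", {
  dw <- double_well_grid(3)
  l <- build_landscape(dw$coords, dw$counts, bins = c(44, 8),
                       smoothing_sigma = 0)
  td <- tidy(l)
  expect_equal(nrow(td), 44 * 8)
  expect_equal(sum(td$occupancy), sum(dw$counts))
  expect_s3_class(autoplot(l), "ggplot")
  expect_equal(glance(l)$total_count, sum(dw$counts))
})
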