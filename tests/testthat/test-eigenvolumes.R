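test_that("two-point PCA gives one component with opposite equal coefficients", {
  fx <- default_fixture()
  vols <- list(render_phantom(fx$spec, -10), render_phantom(fx$spec, 10))
  d <- fit_pca(vols, fx$masks$rp, K = 1)
  expect_equal(d$K, 1)
  expect_equal(d$coefficients[1, 1], -d$coefficients[2, 1], tolerance = 1e-8)
  expect_gt(abs(d$coefficients[1, 1]), 0)
})

test_that("identical volumes make PCA degenerate", {
  fx <- default_fixture()
  vols <- list(fx$ref, fx$ref, fx$ref)
  expect_error(fit_pca(vols, fx$masks$rp, K = 1), "degenerate|identical")
  expect_error(fit_pca(vols[1:3], fx$masks$rp, K = 3), "K")
})

test_that("Gram-matrix PCA equals direct SVD of the centred data (oracle)", {
  set.seed(12)
  vols <- lapply(1:6, function(i) tiny_grid(n = 16, seed = 100 + i))
  m <- array(TRUE, c(16, 16, 16)); m[1, 1, 1] <- TRUE
  mask <- binary_mask(m, 4)
  d <- fit_pca(vols, mask, K = 5)
  X <- t(vapply(vols, function(v) v$data[mask$data], numeric(sum(mask$data))))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  expect_equal(d$eigenvalues, sv$d[1:5]^2, tolerance = 1e-8)
  for (k in 1:5) {
    ev <- d$eigenvolumes[[k]]$data[mask$data]
    # sign-free comparison against the right singular vector
    expect_lt(min(max(abs(ev - sv$v[, k])), max(abs(ev + sv$v[, k]))), 1e-6)
  }
})

test_that("eigenvolumes are orthonormal and K = N-1 reconstructs exactly", {
  fx <- default_fixture()
  thetas <- seq(-20, 20, length.out = 7)
  vols <- lapply(thetas, function(th) render_phantom(fx$spec, th))
  d <- fit_pca(vols, fx$masks$rp, K = 6)
  msk <- fx$masks$rp$data
  E <- vapply(d$eigenvolumes, function(e) e$data[msk], numeric(sum(msk)))
  G <- crossprod(E)
  expect_lt(max(abs(G - diag(6))), 1e-6)
  expect_true(all(diff(d$eigenvalues) <= 1e-9))
  rec <- reconstruct_class(d, 3)
  rms <- sqrt(mean((rec$data[msk] - vols[[3]]$data[msk])^2))
  expect_lt(rms, 1e-5)
})

test_that("the leading coefficient tracks the rotation angle", {
  fx <- default_fixture()
  # within +/-20 deg the rotation arc projects monotonically onto the
  # first mode; at the +/-25 deg extremes the arc curvature folds the
  # chord projection slightly (a geometric property of large rotations)
  thetas <- seq(-20, 20, length.out = 13)
  vols <- lapply(thetas, function(th) render_phantom(fx$spec, th))
  d <- fit_pca(vols, fx$masks$rp, K = 2)
  c1 <- d$coefficients[, 1]
  expect_equal(abs(cor(c1, thetas, method = "spearman")), 1)
  full <- seq(-25, 25, length.out = 17)
  dfull <- fit_pca(lapply(full, function(th) render_phantom(fx$spec, th)),
                   fx$masks$rp, K = 2)
  expect_gte(abs(cor(dfull$coefficients[, 1], full, method = "spearman")),
             0.98)
})

test_that("projection is consistent with fitted coefficients", {
  fx <- default_fixture()
  vols <- lapply(c(-15, -5, 5, 15), function(th) render_phantom(fx$spec, th))
  d <- fit_pca(vols, fx$masks$rp, K = 3)
  expect_equal(project_volume(d$mean_volume, d), rep(0, 3), tolerance = 1e-8)
  expect_equal(project_volume(vols[[2]], d), d$coefficients[2, ],
               tolerance = 1e-6)
  synth <- voxel_grid(d$mean_volume$data + 2 * d$eigenvolumes[[1]]$data,
                      d$mean_volume$voxel_size)
  expect_equal(project_volume(synth, d), c(2, 0, 0), tolerance = 1e-6)
})

test_that("coefficients are invariant to adding a constant to all volumes", {
  fx <- default_fixture()
  vols <- lapply(c(-12, 0, 12), function(th) render_phantom(fx$spec, th))
  shifted <- lapply(vols, function(v)
    voxel_grid(v$data + 7, v$voxel_size))
  d1 <- fit_pca(vols, fx$masks$rp, K = 2)
  d2 <- fit_pca(shifted, fx$masks$rp, K = 2)
  expect_equal(d1$coefficients, d2$coefficients, tolerance = 1e-8)
})

test_that("explained variance behaves for single-mode, full-rank and noise ensembles", {
  fx <- default_fixture()
  # pure small-angle rotation: the arc is nearly linear, one mode dominates
  vols <- lapply(seq(-5, 5, length.out = 9),
                 function(th) render_phantom(fx$spec, th))
  d <- fit_pca(vols, fx$masks$rp, K = 2)
  fr <- explained_variance(d)
  expect_gt(fr[1], 0.95)
  expect_true(all(diff(fr) <= 1e-12))
  # white-noise ensemble: spectrum roughly flat (max/min < 3 at N = 10),
  # and at K = N - 1 the fractions account for all the variance
  nvols <- lapply(1:10, function(i) tiny_grid(n = 16, seed = 200 + i))
  m <- binary_mask(array(TRUE, c(16, 16, 16)), 4)
  dn <- fit_pca(nvols, m, K = 9)
  frn <- explained_variance(dn)
  expect_lt(max(frn) / min(frn), 3)
  expect_equal(sum(frn), 1, tolerance = 1e-9)
})

test_that("the first eigenvolume concentrates inside the mobile-body mask", {
  fx <- default_fixture()
  vols <- lapply(seq(-25, 25, length.out = 9),
                 function(th) render_phantom(fx$spec, th))
  whole <- binary_mask(array(TRUE, dim = fx$ref$shape), fx$ref$voxel_size)
  d <- fit_pca(vols, whole, K = 2)
  e1 <- d$eigenvolumes[[1]]$data
  frac <- sum(e1[fx$masks$rp$data]^2) / sum(e1^2)
  expect_gt(frac, 0.8)
})

test_that("tidy and glance summarise a fit", {
  fx <- default_fixture()
  vols <- lapply(c(-10, 0, 10), function(th) render_phantom(fx$spec, th))
  d <- fit_pca(vols, fx$masks$rp, K = 2)
  td <- tidy(d)
  expect_equal(names(td), c("component", "eigenvalue", "variance_fraction"))
  expect_equal(nrow(td), 2)
  gl <- glance(d)
  expect_equal(gl$n_classes, 3)
})
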