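test_that("phantom rendering is periodic, mass-conserving and linear in weights", {
  spec <- default_fixture()$spec
  v0 <- render_phantom(spec, 0)
  # voxels exactly at the Gaussian evaluation cutoff may flip with the
  # ~1e-14 coordinate rounding of a full turn; their density is < 1e-6
  expect_lt(max(abs(render_phantom(spec, 360)$data - v0$data)), 1e-6)
  masses <- vapply(c(-25, -10, 0, 10, 25), function(th)
    sum(render_phantom(spec, th)$data), numeric(1))
  expect_lt((max(masses) - min(masses)) / mean(masses), 1e-6)
  # linearity: doubling all weights doubles the density
  spec2 <- phantom_spec(cp_atoms = {a <- spec$cp_atoms; a[, 4] <- 2 * a[, 4]; a},
                        rp_atoms = {a <- spec$rp_atoms; a[, 4] <- 2 * a[, 4]; a})
  expect_equal(render_phantom(spec2, 13)$data, 2 * render_phantom(spec, 13)$data,
               tolerance = 1e-12)
})

test_that("theta = 0 renders both bodies unrotated", {
  spec <- default_fixture()$spec
  expect_equal(render_phantom(spec, 0)$data,
               render_body(spec, "cp")$data + render_body(spec, "rp", 0)$data,
               tolerance = 1e-12)
})

test_that("bodies that would leave the box are rejected", {
  far <- cbind(90, 0, 0, 1, 8)
  colnames(far) <- c("x", "y", "z", "weight", "sigma")
  expect_error(phantom_spec(rp_atoms = far), "margin")
})

test_that("flat energy sampling is multinomially uniform (chi-square oracle)", {
  spec <- default_fixture()$spec
  ef <- energy_function("flat", domain = c(-25, 25))
  ens <- make_class_ensemble(spec, ef, n_classes = 20, total_particles = 1e5,
                             seed = 10)
  expect_equal(sum(ens$counts), 1e5)
  p <- stats::chisq.test(ens$counts)$p.value
  expect_gt(p, 0.001)
})

test_that("Boltzmann inversion of sampled counts recovers the energy function", {
  spec <- default_fixture()$spec
  ef <- energy_function("harmonic", domain = c(-25, 25), kappa = 0.02)
  ens <- make_class_ensemble(spec, ef, n_classes = 21, total_particles = 1e5,
                             seed = 11)
  keep <- ens$counts >= 100
  e_obs <- -log(ens$counts[keep] / max(ens$counts))
  e_true <- ef$fn(ens$class_thetas[keep])
  e_true <- e_true - e_true[which.max(ens$counts[keep])]
  expect_lt(sqrt(mean((e_obs - e_true)^2)), 0.1)
})

test_that("ensembles are reproducible under a fixed seed", {
  spec <- default_fixture()$spec
  ef <- energy_function("double_well_barrier", domain = c(-25, 25))
  a <- make_class_ensemble(spec, ef, 11, 5000, seed = 3)
  b <- make_class_ensemble(spec, ef, 11, 5000, seed = 3)
  expect_identical(a$counts, b$counts)
  expect_equal(a$volumes[[5]]$data, b$volumes[[5]]$data)
})

test_that("energy functions honour their declared shapes", {
  ef <- energy_function("double_well_barrier", domain = c(-25, 25),
                        well_centers = c(-15, 15), barrier_height = 3)
  expect_equal(ef$fn(c(-15, 15)), c(0, 0))
  expect_equal(ef$fn(0), 3)
  th <- seq(-25, 25, by = 0.1)
  expect_gte(min(ef$fn(th)), 0)
  efh <- energy_function("harmonic", kappa = 0.02, center = 5)
  expect_equal(efh$fn(5), 0)
  expect_equal(efh$fn(15), 0.5 * 0.02 * 100)
})

test_that("two-state particles honour labels, noise-free images and SNR", {
  spec <- default_fixture()$spec
  # f = 1: all particles in state 1; noise off reproduces pure projections
  ps <- make_two_state_particles(spec, c(25, 0), c(1, 0), n_particles = 10,
                                 snr = Inf, seed = 2)
  expect_true(all(ps$labels == 1L))
  v <- render_phantom(spec, 25)$data
  pr <- volscape:::cpp_project(v, ps$orientations[, 1, drop = FALSE])
  expect_equal(ps$images[, , 1], pr[, , 1], tolerance = 1e-12)

  # empirical SNR within 10% of requested at n = 500
  ps2 <- make_two_state_particles(spec, c(25, 0), c(0.5, 0.5),
                                  n_particles = 500, snr = 2, seed = 9)
  clean <- array(0, dim = dim(ps2$images))
  vols <- list(render_phantom(spec, 25)$data, render_phantom(spec, 0)$data)
  for (s in 1:2) {
    idx <- which(ps2$labels == s)
    clean[, , idx] <- volscape:::cpp_project(vols[[s]],
                                             ps2$orientations[, idx, drop = FALSE])
  }
  noise <- ps2$images - clean
  snr_emp <- stats::var(as.numeric(clean)) / stats::var(as.numeric(noise))
  expect_lt(abs(snr_emp - 2) / 2, 0.1)
})

test_that("particle sets are seeded deterministically and validated", {
  spec <- default_fixture()$spec
  a <- make_two_state_particles(spec, c(25, 0), c(0.4, 0.6), 12, snr = 2, seed = 5)
  b <- make_two_state_particles(spec, c(25, 0), c(0.4, 0.6), 12, snr = 2, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_equal(a$images, b$images)
  expect_error(make_two_state_particles(spec, c(25, 0), c(0.4, 0.6), 5),
               "n_particles")
  expect_error(make_two_state_particles(spec, c(25, 0), c(0.7, 0.6), 12),
               "fractions|sum")
})
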