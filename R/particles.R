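#' Simulate a two-state particle image set
#'
#' Generates noisy 2D projection images of a phantom frozen in one of two
#' rotation states, the fixture for competitive two-state classification.
#' Each particle draws its state from `fractions`, is projected along a
#' uniformly random orientation, and receives additive white Gaussian
#' noise with variance `signal_variance / snr` (the signal variance is
#' measured per particle on its noiseless projection). Ground-truth labels
#' and orientations are returned for evaluation only.
#'
#' The simulated images are CTF-free: the experimental protocol this
#' emulates corrects the contrast transfer function per particle before
#' classification, so the classifier operates downstream of that step.
#'
#' @param spec a [phantom_spec()].
#' @param theta_states numeric length-2: the rotation angle (degrees) of
#'   state 1 and state 2.
#' @param fractions numeric length-2 summing to 1: probability of each state.
#' @param n_particles number of particles (>= 10).
#' @param snr signal-to-noise ratio (variance ratio); `Inf` for noise-free.
#' @param seed integer RNG seed.
#' @param exact_fraction if `TRUE`, the set contains exactly
#'   `round(fractions[1] * n_particles)` state-1 particles in a seeded
#'   random order, so the ground-truth fraction of the generated set equals
#'   the request; by default states are drawn independently
#'   (Bernoulli), so the realised fraction fluctuates binomially.
#' @return A list of class `particle_set`: `images` (box x box x n array),
#'   `labels` (1 or 2, per particle), `thetas`, `orientations` (9 x n
#'   flattened rotation matrices), `voxel_size`, `truth`.
#' @export
make_two_state_particles <- function(spec, theta_states, fractions = c(0.5, 0.5),
                                     n_particles = 400, snr = 2, seed = 1L,
                                     exact_fraction = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), length(theta_states) == 2,
            length(fractions) == 2, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, n_particles >= 10, snr > 0)
  set.seed(seed)
  labels <- if (exact_fraction) {
    n1 <- round(fractions[1] * n_particles)
    sample(rep(c(1L, 2L), times = c(n1, n_particles - n1)))
  } else 1L + (stats::runif(n_particles) >= fractions[1])
  rots <- random_rotations(n_particles)
  vols <- lapply(theta_states, function(th) render_phantom(spec, th)$data)
  images <- array(0, dim = c(spec$box, spec$box, n_particles))
  for (s in 1:2) {
    idx <- which(labels == s)
    if (length(idx))
      images[, , idx] <- cpp_project(vols[[s]], rots[, idx, drop = FALSE])
  }
  if (is.finite(snr)) {
    for (i in seq_len(n_particles)) {
      sv <- stats::var(as.numeric(images[, , i]))
      images[, , i] <- images[, , i] +
        stats::rnorm(spec$box^2, sd = sqrt(sv / snr))
    }
  }
  structure(
    list(images = images, labels = labels,
         thetas = theta_states[labels], orientations = rots,
         voxel_size = spec$voxel_size,
         truth = list(spec = spec, theta_states = theta_states,
                      fractions = fractions, snr = snr, seed = seed)),
    class = "particle_set"
  )
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, box %d, states %g / %g deg (snr %g)\n",
              dim(x$images)[3], dim(x$images)[1],
              x$truth$theta_states[1], x$truth$theta_states[2], x$truth$snr))
  invisible(x)
}

#' Write a particle set as an MRC stack plus truth TSV
#'
#' @param particles a `particle_set`.
#' @param dir output directory.
#' @return Invisibly, the paths written (`particles.mrc`, `truth.tsv`).
#' @export
write_particles <- function(particles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stack_path <- file.path(dir, "particles.mrc")
  write_stack(particles$images, particles$voxel_size, stack_path)
  truth <- tibble::tibble(
    particle_id = seq_along(particles$labels),
    state = particles$labels,
    theta_true = particles$thetas,
    q = apply(particles$orientations, 2, paste, collapse = ",")
  )
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(truth, truth_path)
  invisible(c(stack = stack_path, truth = truth_path))
}
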