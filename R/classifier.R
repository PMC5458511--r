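#' Iterative competitive two-state classification of particle images
#'
#' Each particle is aligned against projection libraries of a "rotated"
#' and a "non-rotated" reference volume and assigned to the better-fitting
#' reference by normalised cross-correlation (full-image, zero-mean,
#' unit-norm). After each iteration new volumes are reconstructed from the
#' assigned particles by weighted backprojection, low-pass filtered to a
#' common resolution and normalised, and the next iteration re-matches
#' against the updated references. Three iterations is the default
#' protocol. Exact score ties are assigned to the non-rotated state.
#'
#' Matching per particle and reference: best over a quasi-uniform viewing
#' direction grid (`orientation_grid_step`) times an in-plane rotation grid
#' (`inplane_step`), scored at zero shift, then the winning orientation is
#' re-scored over integer shifts up to `shift_range` pixels via windowed
#' FFT cross-correlation.
#'
#' @param particles a `particle_set` (see [make_two_state_particles()]) or
#'   a box x box x n numeric array.
#' @param ref_rotated,ref_nonrotated reference [voxel_grid()]s on a common
#'   grid.
#' @param orientation_grid_step viewing-direction spacing, degrees.
#' @param inplane_step in-plane rotation spacing, degrees.
#' @param shift_range maximum integer shift searched, pixels.
#' @param iterations number of competitive iterations (>= 1).
#' @param lowpass resolution (Angstrom) to which reconstructions are
#'   filtered each iteration. The default, 2.25 voxels, keeps the whole
#'   discriminative band: coarser comparison resolutions were found to
#'   destabilise the iteration for strongly unbalanced mixtures (the
#'   minority reference loses borderline particles each round).
#' @return An object of class `two_state_result`: `assignments` (n x
#'   iterations matrix, values `"rotated"`/`"non_rotated"`),
#'   `best_orientation` (9 x n flattened matrices, final iteration),
#'   `counts` (tibble: iteration, n_rotated, n_non_rotated),
#'   `fraction_rotated` (final), `refs_final` (list of two
#'   [voxel_grid()]s), `degenerate` flag, `scores` (final per-particle
#'   best score per reference).
#' @export
classify_two_state <- function(particles, ref_rotated, ref_nonrotated,
                               orientation_grid_step = 15, inplane_step = 10,
                               shift_range = 3, iterations = 3,
                               lowpass = NULL) {
  imgs <- if (inherits(particles, "particle_set")) particles$images
          else particles
  stopifnot(is.array(imgs), length(dim(imgs)) == 3L, iterations >= 1)
  check_same_grid(ref_rotated, ref_nonrotated)
  vsz <- ref_rotated$voxel_size
  if (is.null(lowpass)) lowpass <- 2.25 * vsz
  box <- dim(imgs)[1]
  n <- dim(imgs)[3]
  degenerate <- max(abs(ref_rotated$data - ref_nonrotated$data)) == 0
  if (degenerate)
    warning("identical references: all assignments tie to non_rotated",
            call. = FALSE)

  dirs <- orientation_grid(orientation_grid_step)
  inplane <- seq(0, 360 - inplane_step, by = inplane_step)
  # particles are matched at the same resolution as the references
  imgs_f <- imgs
  for (i in seq_len(n))
    imgs_f[, , i] <- low_pass_image(imgs[, , i], vsz, lowpass)
  # normalised particle matrix (pixels x n)
  P <- matrix(imgs_f, box * box, n)
  P <- sweep(P, 2, colMeans(P))
  pnorm <- sqrt(colSums(P^2)); pnorm[pnorm == 0] <- 1
  Pn <- sweep(P, 2, pnorm, "/")

  refs <- list(rotated = ref_rotated, non_rotated = ref_nonrotated)
  assignments <- matrix(NA_character_, n, iterations)
  counts <- vector("list", iterations)
  frozen <- c(rotated = FALSE, non_rotated = FALSE)
  best_orient <- matrix(0, 9, n)
  final_scores <- matrix(0, n, 2, dimnames = list(NULL, names(refs)))

  for (it in seq_len(iterations)) {
    volf <- lapply(refs, function(r) low_pass(r, lowpass)$data)
    lib <- lapply(volf, function(v) projection_library(v, dirs, inplane))
    # coarse: max normalised dot product over the library, per particle
    sc <- lapply(lib, function(L) {
      s <- crossprod(L$mat, Pn)            # (n_lib x n)
      k <- max.col(t(s), ties.method = "first")
      list(score = s[cbind(k, seq_len(n))], k = k,
           orient = L$orient[, k, drop = FALSE])
    })
    # refine: continuous orientation polish from the coarse optimum, then
    # integer shifts via windowed FFT cross-correlation
    for (ref_i in 1:2) {
      for (i in seq_len(n)) {
        rr <- refine_orientation(Pn[, i], volf[[ref_i]],
                                 matrix(sc[[ref_i]]$orient[, i], 3, 3))
        if (rr$score >= sc[[ref_i]]$score[i]) {
          sc[[ref_i]]$score[i] <- rr$score
          sc[[ref_i]]$orient[, i] <- as.numeric(rr$R)
          ssc <- shift_score(Pn[, i], rr$proj, box, shift_range)
          sc[[ref_i]]$score[i] <- max(sc[[ref_i]]$score[i], ssc)
        }
      }
    }
    rot_wins <- sc[[1]]$score > sc[[2]]$score   # ties -> non_rotated
    assignments[, it] <- ifelse(rot_wins, "rotated", "non_rotated")
    counts[[it]] <- tibble::tibble(iteration = it,
                                   n_rotated = sum(rot_wins),
                                   n_non_rotated = sum(!rot_wins))
    for (s in 1:2) {
      idx <- if (s == 1) which(rot_wins) else which(!rot_wins)
      if (length(idx))
        best_orient[, idx] <- sc[[s]]$orient[, idx, drop = FALSE]
    }
    final_scores[, 1] <- sc[[1]]$score
    final_scores[, 2] <- sc[[2]]$score
    if (it < iterations) {
      for (s in c("rotated", "non_rotated")) {
        idx <- which(assignments[, it] == s)
        if (length(idx) < 3) {
          if (!frozen[s])
            warning("class '", s, "' emptied out at iteration ", it,
                    "; freezing its reference", call. = FALSE)
          frozen[s] <- TRUE
          next
        }
        rec <- reconstruct_backprojection(imgs[, , idx, drop = FALSE],
                                          best_orient[, idx, drop = FALSE],
                                          voxel_size = vsz)
        refs[[s]] <- normalize_map(low_pass(rec, lowpass))
      }
    }
  }
  counts <- dplyr::bind_rows(counts)
  structure(
    list(assignments = assignments, best_orientation = best_orient,
         counts = counts,
         fraction_rotated = counts$n_rotated[iterations] / n,
         refs_final = refs, degenerate = degenerate, scores = final_scores),
    class = "two_state_result"
  )
}

#' @export
print.two_state_result <- function(x, ...) {
  cat("<two_state_result>\n")
  print(x$counts)
  cat(sprintf("final fraction rotated: %.3f%s\n", x$fraction_rotated,
              if (x$degenerate) " (degenerate: identical references)" else ""))
  invisible(x)
}

# Projection library of one reference: all viewing directions x in-plane
# angles, as a (pixels x n_lib) matrix of zero-mean unit-norm columns,
# with the composed orientation matrix per column.
projection_library <- function(vol, dirs, inplane) {
  box <- dim(vol)[1]
  proj <- cpp_project(vol, dirs)
  nd <- ncol(dirs); na <- length(inplane)
  mat <- matrix(0, box * box, nd * na)
  orient <- matrix(0, 9, nd * na)
  for (a in seq_along(inplane)) {
    rotimg <- if (inplane[a] == 0) proj else cpp_rotate_stack(proj, inplane[a])
    cols <- (a - 1) * nd + seq_len(nd)
    mat[, cols] <- matrix(rotimg, box * box, nd)
    Rz <- rot_axis_angle(c(0, 0, 1), inplane[a])
    for (d in seq_len(nd))
      orient[, (a - 1) * nd + d] <-
        as.numeric(Rz %*% matrix(dirs[, d], 3, 3))
  }
  mat <- sweep(mat, 2, colMeans(mat))
  nrm <- sqrt(colSums(mat^2)); nrm[nrm == 0] <- 1
  list(mat = sweep(mat, 2, nrm, "/"), orient = orient)
}

# Continuous orientation polish: Nelder-Mead over a small rotation
# perturbation Rx(a) Ry(b) Rz(c) applied to the coarse orientation,
# maximising the normalised correlation between the (normalised) particle
# and the on-the-fly projection of the filtered reference volume.
refine_orientation <- function(pvec, vol, R0, maxit = 45) {
  obj <- function(par) {
    R <- rot_axis_angle(c(1, 0, 0), par[1]) %*%
      rot_axis_angle(c(0, 1, 0), par[2]) %*%
      rot_axis_angle(c(0, 0, 1), par[3]) %*% R0
    pr <- as.numeric(cpp_project(vol, matrix(as.numeric(R), 9, 1)))
    pr <- pr - mean(pr)
    nr <- sqrt(sum(pr^2))
    if (nr == 0) return(1)
    -sum(pvec * pr) / nr
  }
  opt <- stats::optim(c(0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  R <- rot_axis_angle(c(1, 0, 0), opt$par[1]) %*%
    rot_axis_angle(c(0, 1, 0), opt$par[2]) %*%
    rot_axis_angle(c(0, 0, 1), opt$par[3]) %*% R0
  pr <- as.numeric(cpp_project(vol, matrix(as.numeric(R), 9, 1)))
  pr <- pr - mean(pr)
  nr <- sqrt(sum(pr^2))
  list(score = -opt$value, R = R, proj = if (nr > 0) pr / nr else pr)
}

# Best NCC over integer shifts within +/- shift_range pixels between a
# normalised particle and a normalised projection, via circular FFT
# correlation restricted to the shift window; directly comparable with the
# zero-shift score.
shift_score <- function(pvec, projvec, box, shift_range) {
  if (shift_range < 1) return(-Inf)
  w <- c(seq_len(shift_range + 1), box - rev(seq_len(shift_range)) + 1)
  A <- matrix(pvec, box, box)
  B <- matrix(projvec, box, box)
  cc <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE)) /
    (box * box)
  max(cc[w, w])
}

#' Reconstruct a volume from images by real-space backprojection
#'
#' Smears each image back along its viewing axis and normalises by the
#' coverage map (with a floor at 10% of the mean coverage to avoid
#' division blow-up at poorly covered voxels). Simple backprojection is
#' adequate at phantom box sizes; it is not a Fourier-gridded
#' reconstruction and attenuates high frequencies accordingly.
#'
#' @param images box x box x n array (n >= 3).
#' @param orientations 9 x n matrix of flattened rotation matrices (the
#'   matrices used to project).
#' @param voxel_size Angstrom per voxel of the output grid.
#' @return A [voxel_grid()].
#' @export
reconstruct_backprojection <- function(images, orientations, voxel_size = 1,
                                       ramp = TRUE, weights = NULL) {
  stopifnot(is.array(images), length(dim(images)) == 3L)
  n <- dim(images)[3]
  if (n < 3) stop("need at least 3 images to reconstruct", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (sum(weights) == 0) weights <- rep(1, n)
  # degenerate orientation coverage: all viewing axes (third rows) parallel
  axes <- orientations[c(3, 6, 9), , drop = FALSE]
  dots <- abs(colSums(axes * axes[, 1]))
  if (all(dots > 0.999))
    warning("degenerate orientation coverage: all views share one axis",
            call. = FALSE)
  if (ramp) {
    # 2D ramp (|f|) pre-filter compensating the 1/|f| sampling density of
    # backprojection in Fourier space (parallel-beam weighting)
    box <- dim(images)[1]
    fx <- c(0:floor(box / 2), -(ceiling(box / 2) - 1):-1)[seq_len(box)] / box
    w <- sqrt(outer(fx^2, fx^2, "+"))
    for (i in seq_len(n))
      images[, , i] <- Re(stats::fft(stats::fft(images[, , i]) * w,
                                     inverse = TRUE)) / (box * box)
  }
  bp <- cpp_backproject(images, orientations, weights)
  cov <- bp$coverage
  floor_ <- 0.1 * mean(cov)
  vol <- bp$volume / pmax(cov, floor_)
  voxel_grid(vol, voxel_size)
}
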