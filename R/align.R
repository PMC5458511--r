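#' Rigid transform utilities
#'
#' A rigid transform holds a 3x3 rotation (det +1) and a translation in
#' Angstrom, acting about the box centre: first rotate, then translate.
#'
#' @param rotation 3x3 orthonormal matrix.
#' @param translation numeric 3-vector, Angstrom.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must have determinant +1", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param a,b `rigid_transform`s; `compose_transform(a, b)` applies `b`
#'   first, then `a`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @param x a `rigid_transform`.
#' @export
invert_transform <- function(x) {
  rigid_transform(t(x$rotation), -as.numeric(t(x$rotation) %*% x$translation))
}

#' Apply a rigid transform to a volume
#'
#' Resamples with trilinear interpolation; the rotation acts about the
#' geometric box centre, then the map is shifted by the translation.
#'
#' @param grid a [voxel_grid()].
#' @param transform a [rigid_transform()] (translation in Angstrom).
#' @return The transformed [voxel_grid()].
#' @export
apply_transform <- function(grid, transform) {
  stopifnot(inherits(grid, "voxel_grid"))
  out <- cpp_rigid_resample(grid$data, transform$rotation,
                            transform$translation / grid$voxel_size)
  voxel_grid(out, grid$voxel_size, grid$origin)
}

#' Align a volume to a reference over a masked region
#'
#' Exhaustive search over a grid of rotations (z-y-z Euler angles) and
#' integer voxel shifts, maximising the normalised cross-correlation (NCC)
#' computed over `region` in the reference frame, followed by local
#' quadratic interpolation of the angle and shift grids. This is how class
#' volumes are brought into a common frame using the fixed subcomplex
#' (e.g. the 20S core particle) only.
#'
#' @param volume,reference [voxel_grid()]s on the same grid.
#' @param region a [binary_mask()] selecting the alignment region.
#' @param ang_range half-range of each Euler angle, degrees.
#' @param ang_step angular grid step, degrees.
#' @param shift_range half-range of the shift search, Angstrom.
#' @param score_floor NCC below which the result is flagged low-confidence.
#' @return A list of class `alignment`: `transform` (a [rigid_transform()]
#'   mapping `volume` into the reference frame), `aligned` (the resampled
#'   [voxel_grid()]), `score` (masked NCC in \[-1, 1\]) and `low_score` flag.
#' @export
align_to_reference <- function(volume, reference, region,
                               ang_range = 6, ang_step = 2,
                               shift_range = 8, score_floor = 0.2) {
  check_same_grid(volume, reference)
  check_same_grid(volume, region)
  if (!inherits(region, "binary_mask")) stop("`region` must be a binary_mask",
                                             call. = FALSE)
  midx <- which(region$data, arr.ind = TRUE) - 1L   # 0-based for C++
  refvals <- reference$data[region$data]
  if (stats::sd(refvals) == 0)
    stop("reference is constant inside the alignment region", call. = FALSE)
  angs <- seq(-ang_range, ang_range, by = ang_step)
  smax <- max(0L, floor(shift_range / volume$voxel_size))
  sgrid <- -smax:smax
  shifts <- as.matrix(expand.grid(sx = sgrid, sy = sgrid, sz = sgrid))
  storage.mode(shifts) <- "integer"
  na <- length(angs)
  scores <- array(-Inf, dim = c(na, na, na))
  best <- list(score = -Inf)
  for (ia in seq_len(na)) for (ib in seq_len(na)) for (ic in seq_len(na)) {
    R <- euler_zyz(angs[ia], angs[ib], angs[ic])
    res <- cpp_rigid_resample(volume$data, R, c(0, 0, 0))
    # value of the shifted map at mask voxel p is res(p - t): probe -t
    ncc <- cpp_masked_ncc_shifts(res, midx, refvals, -shifts)
    k <- which.max(ncc)
    scores[ia, ib, ic] <- ncc[k]
    if (ncc[k] > best$score)
      best <- list(score = ncc[k], ia = ia, ib = ib, ic = ic,
                   shift = shifts[k, ], res = res, ncc = ncc)
  }
  # quadratic sub-step refinement of each Euler angle on the score grid
  refine_axis <- function(i, vals) {
    if (i <= 1 || i >= length(vals)) return(0)
    parabolic_offset(vals[i - 1], vals[i], vals[i + 1])
  }
  da <- refine_axis(best$ia, scores[, best$ib, best$ic]) * ang_step
  db <- refine_axis(best$ib, scores[best$ia, , best$ic]) * ang_step
  dc <- refine_axis(best$ic, scores[best$ia, best$ib, ]) * ang_step
  R <- euler_zyz(angs[best$ia] + da, angs[best$ib] + db, angs[best$ic] + dc)
  # sub-voxel shift refinement along each axis at the best rotation
  tvox <- as.numeric(best$shift)
  for (ax in 1:3) {
    probe <- function(d) {
      s <- tvox; s[ax] <- s[ax] + d
      m <- matrix(as.integer(round(-s)), 1, 3)
      cpp_masked_ncc_shifts(best$res, midx, refvals, m)
    }
    if (abs(tvox[ax]) < smax)
      tvox[ax] <- tvox[ax] + parabolic_offset(probe(-1), probe(0), probe(1))
  }
  # continuous local polish of angles and shifts around the interpolated
  # optimum (the NCC surface is smooth at phantom scale)
  par0 <- c(angs[best$ia] + da, angs[best$ib] + db, angs[best$ic] + dc, tvox)
  ncc_at <- function(par) {
    res <- cpp_rigid_resample(volume$data, euler_zyz(par[1], par[2], par[3]),
                              par[4:6])
    av <- res[region$data]
    if (stats::sd(av) == 0) return(1)      # minimiser: worst score
    -stats::cor(refvals, av)
  }
  opt <- stats::optim(par0, ncc_at, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-10))
  if (-opt$value >= best$score) par0 <- opt$par
  R <- euler_zyz(par0[1], par0[2], par0[3])
  tvox <- par0[4:6]
  transform <- rigid_transform(R, tvox * volume$voxel_size)
  aligned <- apply_transform(volume, transform)
  avals <- aligned$data[region$data]
  score <- if (stats::sd(avals) > 0) stats::cor(refvals, avals) else 0
  structure(list(transform = transform, aligned = aligned, score = score,
                 low_score = score < score_floor),
            class = "alignment")
}

#' Estimate the mobile-subcomplex rotation angle of an aligned volume
#'
#' With the fixed subcomplex already aligned, the rotation of the mobile
#' subcomplex (RP) is the angle `theta` that maximises the NCC, inside
#' `rp_mask`, between the reference rotated by `theta` about `axis` and
#' the aligned volume. A quadratic sub-step refinement on the angle grid
#' gives sub-degree precision. Positive angles follow the right-handed
#' convention about `axis`.
#'
#' @param aligned a [voxel_grid()] already in the reference frame.
#' @param reference the reference [voxel_grid()] (mobile body at 0 degrees).
#' @param rp_mask [binary_mask()] covering the mobile subcomplex over its
#'   rotation range.
#' @param axis rotation axis (unit 3-vector), default the long axis +z.
#' @param range half-range of the angle search, degrees.
#' @param step angle grid step, degrees.
#' @return `theta_hat` in degrees (scalar, with attribute `profile`:
#'   a tibble of the NCC profile).
#' @export
estimate_rp_rotation <- function(aligned, reference, rp_mask,
                                 axis = c(0, 0, 1), range = 30, step = 0.5) {
  check_same_grid(aligned, reference)
  check_same_grid(aligned, rp_mask)
  msk <- rp_mask$data
  avals <- aligned$data[msk]
  thetas <- seq(-range, range, by = step)
  prof <- vapply(thetas, function(th) {
    rot <- cpp_rigid_resample(reference$data, rot_axis_angle(axis, th),
                              c(0, 0, 0))
    rv <- rot[msk]
    if (stats::sd(rv) == 0 || stats::sd(avals) == 0) return(0)
    stats::cor(rv, avals)
  }, numeric(1))
  if (max(prof) - min(prof) < 1e-3)
    stop("flat correlation profile: rotation angle is indeterminate",
         call. = FALSE)
  i <- which.max(prof)
  off <- if (i > 1 && i < length(prof))
    parabolic_offset(prof[i - 1], prof[i], prof[i + 1]) else 0
  theta_hat <- thetas[i] + off * step
  attr(theta_hat, "profile") <- tibble::tibble(theta = thetas, ncc = prof)
  theta_hat
}

#' Align every class volume of an ensemble to a reference
#'
#' Batch driver over a manifest: each class map is read and aligned on the
#' fixed-subcomplex mask with [align_to_reference()]. Unreadable maps are
#' collected as per-class errors and reported at the end; the run continues.
#'
#' @param manifest tibble with `class_id`, `map_path`, `n_particles` (see
#'   [read_manifest()]), or a `class_ensemble` whose volumes are in memory.
#' @param reference reference [voxel_grid()].
#' @param cp_mask [binary_mask()] of the fixed subcomplex.
#' @param rp_mask optional [binary_mask()] of the mobile subcomplex, carried
#'   along for downstream PCA / rotation estimation.
#' @param ... search parameters passed to [align_to_reference()].
#' @return An object of class `aligned_ensemble`: `volumes` (list of
#'   aligned [voxel_grid()]s), `transforms` (tibble: class_id, r11..r33,
#'   t1..t3, score, low_score), `counts`, `cp_mask`, `rp_mask`.
#' @export
align_ensemble <- function(manifest, reference, cp_mask, rp_mask = NULL, ...) {
  if (inherits(manifest, "class_ensemble")) {
    vols <- manifest$volumes
    ids <- seq_along(vols)
    counts <- manifest$counts
  } else {
    ids <- manifest$class_id
    counts <- manifest$n_particles
    vols <- vector("list", length(ids))
    errors <- character()
    for (i in seq_along(ids)) {
      vols[[i]] <- tryCatch(read_map(manifest$map_path[i]),
                            error = function(e) conditionMessage(e))
    }
  }
  aligned <- vector("list", length(vols))
  rows <- vector("list", length(vols))
  errors <- character()
  for (i in seq_along(vols)) {
    if (is.character(vols[[i]])) { errors <- c(errors, vols[[i]]); next }
    al <- align_to_reference(vols[[i]], reference, cp_mask, ...)
    aligned[[i]] <- al$aligned
    R <- al$transform$rotation
    rows[[i]] <- tibble::tibble(
      class_id = ids[i],
      r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
      r21 = R[2, 1], r22 = R[2, 2], r23 = R[2, 3],
      r31 = R[3, 1], r32 = R[3, 2], r33 = R[3, 3],
      t1 = al$transform$translation[1], t2 = al$transform$translation[2],
      t3 = al$transform$translation[3],
      score = al$score, low_score = al$low_score
    )
  }
  if (length(errors))
    stop("failed to align ", length(errors), " class(es):\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  structure(
    list(volumes = aligned, transforms = dplyr::bind_rows(rows),
         counts = counts, cp_mask = cp_mask, rp_mask = rp_mask),
    class = "aligned_ensemble"
  )
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat(sprintf("<aligned_ensemble> %d classes, mean NCC %.3f\n",
              length(x$volumes), mean(x$transforms$score)))
  invisible(x)
}
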