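#' Specify a two-rigid-body phantom
#'
#' Defines a synthetic two-body complex in the spirit of the 26S proteasome:
#' a fixed barrel-like core particle (CP) and a mobile regulatory particle
#' (RP) that rotates as a rigid body about the long axis. Both bodies are
#' sums of Gaussian pseudo-atoms. The default CP deliberately carries
#' off-axis features: a core built only of on-axis Gaussians would be
#' exactly rotationally symmetric about the long axis, which would make the
#' rotated-state map a global rotation of the non-rotated one and leave the
#' azimuth unconstrained when aligning on the CP alone.
#'
#' @param box voxels per side of the cubic grid.
#' @param voxel_size Angstrom per voxel.
#' @param cp_atoms,rp_atoms matrices with columns `x, y, z, weight, sigma`
#'   (Angstrom, relative to the box centre; `sigma` is the Gaussian width).
#' @param axis unit 3-vector, the rotation (long) axis; default +z.
#' @param seed integer seed recorded with the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(box = 48, voxel_size = 4,
                         cp_atoms = default_cp_atoms(),
                         rp_atoms = default_rp_atoms(),
                         axis = c(0, 0, 1), seed = 1L) {
  stopifnot(box >= 8, voxel_size > 0,
            is.matrix(cp_atoms), ncol(cp_atoms) == 5, nrow(cp_atoms) >= 1,
            is.matrix(rp_atoms), ncol(rp_atoms) == 5, nrow(rp_atoms) >= 1)
  axis <- axis / sqrt(sum(axis^2))
  spec <- structure(
    list(box = as.integer(box), voxel_size = voxel_size,
         cp_atoms = cp_atoms, rp_atoms = rp_atoms,
         axis = axis, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  check_phantom_fit(spec)
  spec
}

# Bodies must fit in the box with >= 4 voxels margin at any rotation about
# the axis; the body extent is atom centres + 2 sigma.
check_phantom_fit <- function(spec) {
  half <- spec$box * spec$voxel_size / 2
  margin <- 4 * spec$voxel_size
  for (atoms in list(spec$cp_atoms, spec$rp_atoms)) {
    r <- sqrt(rowSums(atoms[, 1:3, drop = FALSE]^2)) + 2 * atoms[, 5]
    if (any(r > half - margin))
      stop("phantom body leaves the box (needs a 4-voxel margin at any ",
           "rotation); enlarge the box or shrink the body", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname phantom_spec
#' @export
default_cp_atoms <- function() {
  core <- cbind(0, 0, seq(-56, -8, by = 12), 2.0, 10)
  az <- seq(0, 300, by = 60) * pi / 180
  ring1 <- cbind(24 * cos(az), 24 * sin(az), -48, 1.0, 8)
  ring2 <- cbind(24 * cos(az), 24 * sin(az), -16, 1.0, 8)
  # azimuthal asymmetry: a ridge at azimuth 0 so CP-only alignment fixes
  # the azimuth and the two conformational states are not globally related
  ridge <- cbind(30, 0, c(-52, -40, -28, -16), 1.5, 7)
  out <- rbind(core, ring1, ring2, ridge)
  colnames(out) <- c("x", "y", "z", "weight", "sigma")
  out
}

#' @rdname phantom_spec
#' @export
default_rp_atoms <- function() {
  out <- rbind(
    # large peripheral lobe A: most of the rotation contrast lives here
    c(40, 0, 16, 3.0, 7), c(42, 6, 26, 3.0, 7), c(36, -8, 22, 2.6, 7),
    # lobe B at a different azimuth and height (asymmetric cluster)
    c(-30, 24, 20, 2.2, 7), c(-32, 19, 30, 2.2, 7),
    # peripheral arm at a third azimuth
    c(-12, -33, 36, 1.8, 7), c(0, -38, 26, 1.8, 7),
    # small axial cap connecting the lobes
    c(0, 0, 20, 1.0, 9), c(0, 0, 34, 1.0, 9), c(0, 0, 46, 0.8, 8)
  )
  colnames(out) <- c("x", "y", "z", "weight", "sigma")
  out
}

#' Render a phantom at a given mobile-body rotation angle
#'
#' The CP atoms are rendered at their fixed coordinates; the RP atoms are
#' first rotated by `theta` degrees about the spec's axis through the box
#' centre. Density is the sum of the Gaussian pseudo-atoms.
#'
#' @param spec a [phantom_spec()].
#' @param theta rotation of the mobile body in degrees.
#' @return A [voxel_grid()].
#' @export
render_phantom <- function(spec, theta = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  rp <- rotate_atoms(spec$rp_atoms, spec$axis, theta)
  render_atoms(rbind(spec$cp_atoms, rp), spec)
}

#' @rdname render_phantom
#' @param body which body to render alone (used for mask construction).
#' @export
render_body <- function(spec, body = c("cp", "rp"), theta = 0) {
  body <- match.arg(body)
  atoms <- if (body == "cp") spec$cp_atoms
           else rotate_atoms(spec$rp_atoms, spec$axis, theta)
  render_atoms(atoms, spec)
}

rotate_atoms <- function(atoms, axis, theta) {
  R <- rot_axis_angle(axis, theta)
  out <- atoms
  out[, 1:3] <- atoms[, 1:3, drop = FALSE] %*% t(R)
  out
}

render_atoms <- function(atoms, spec) {
  a <- atoms
  a[, 1:3] <- a[, 1:3] / spec$voxel_size     # to voxel units
  a[, 5] <- a[, 5] / spec$voxel_size
  dat <- cpp_render_gaussians(spec$box, a)
  voxel_grid(dat, spec$voxel_size)
}

#' Build CP / RP region masks for a phantom
#'
#' The CP mask is the support of the CP body; the RP mask is the union of
#' the RP support over a range of rotation angles, so a rotated RP stays
#' inside its mask. Support is density above `threshold` times the body
#' maximum.
#'
#' @param spec a [phantom_spec()].
#' @param theta_range angles (degrees) whose RP supports are unioned.
#' @param threshold relative density threshold defining support.
#' @return A list with `cp` and `rp` [binary_mask()]s.
#' @export
phantom_masks <- function(spec, theta_range = c(-30, 30), threshold = 0.05) {
  cp <- render_body(spec, "cp")
  cp_mask <- binary_mask(cp$data > threshold * max(cp$data), spec$voxel_size)
  thetas <- seq(theta_range[1], theta_range[2], length.out = 7)
  acc <- array(FALSE, dim = rep(spec$box, 3))
  for (th in thetas) {
    rp <- render_body(spec, "rp", theta = th)
    acc <- acc | (rp$data > threshold * max(rp$data))
  }
  list(cp = cp_mask, rp = binary_mask(acc, spec$voxel_size))
}
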