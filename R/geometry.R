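# Rotation utilities. Convention throughout: right-handed rotations,
# angles in degrees, positive = counterclockwise looking down the +axis;
# rotations act about the geometric box centre.

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric 3-vector (normalised internally).
#' @param deg rotation angle in degrees (right-handed about `axis`).
#' @return 3x3 rotation matrix.
#' @export
rot_axis_angle <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, uz, -uy, -uz, 0, ux, uy, -ux, 0), 3, 3)
  diag(3) + sa * K + (1 - ca) * (K %*% K)
}

# Euler z-y-z rotation (degrees): R = Rz(a) Ry(b) Rz(c)
euler_zyz <- function(a, b, c) {
  rot_axis_angle(c(0, 0, 1), a) %*% rot_axis_angle(c(0, 1, 0), b) %*%
    rot_axis_angle(c(0, 0, 1), c)
}

# Unit quaternion (w,x,y,z) to rotation matrix
quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# n uniformly random rotation matrices (uses the current RNG stream),
# returned as a 9 x n matrix of column-major flattened 3x3 matrices.
random_rotations <- function(n) {
  out <- matrix(0, 9, n)
  for (i in seq_len(n)) {
    q <- stats::rnorm(4)
    out[, i] <- as.numeric(quat_to_mat(q))
  }
  out
}

# Quasi-uniform viewing directions: Fibonacci sphere lattice with an
# angular spacing of roughly `step_deg`. Returns a 9 x n matrix of
# orientation matrices whose third row is the viewing direction (so the
# object rotated by R and projected along lab z is viewed along that
# direction in the object frame).
orientation_grid <- function(step_deg) {
  n <- max(4L, ceiling(4 * pi / (step_deg * pi / 180)^2))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)           # polar angle
  theta <- pi * (1 + sqrt(5)) * i      # golden-angle azimuth
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  out <- matrix(0, 9, n)
  for (m in seq_len(n)) {
    d <- dirs[m, ]
    # build a right-handed orthonormal frame with d as the third row
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- ref - sum(ref * d) * d
    u <- u / sqrt(sum(u^2))
    v <- c(d[2] * u[3] - d[3] * u[2],
           d[3] * u[1] - d[1] * u[3],
           d[1] * u[2] - d[2] * u[1])
    out[, m] <- as.numeric(rbind(u, v, d))
  }
  out
}

# 1D parabolic (quadratic) peak interpolation around a grid maximum.
# Returns the sub-grid offset in units of the grid step, clamped to
# [-0.5, 0.5]; 0 when the vertex is at a boundary or degenerate.
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || denom >= 0) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, off))
}
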