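#' Low-pass filter a map in Fourier space
#'
#' Attenuates Fourier amplitudes beyond `1/resolution` with a soft
#' cosine-edged cutoff (edge width two Fourier shells). The DC term, and
#' hence the mean density, is preserved. Competing reconstructions are
#' brought "to the same resolution" with this filter before normalisation.
#'
#' @param grid a [voxel_grid()] (also works on a 2D image matrix via
#'   `low_pass_image()`).
#' @param resolution target resolution in Angstrom; must be at least twice
#'   the voxel size (Nyquist).
#' @return A filtered [voxel_grid()].
#' @export
low_pass <- function(grid, resolution) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (resolution < 2 * grid$voxel_size)
    stop("resolution ", resolution, " A is below Nyquist (",
         2 * grid$voxel_size, " A)", call. = FALSE)
  filt <- fourier_filter_nd(dim(grid$data), grid$voxel_size, resolution)
  out <- Re(stats::fft(stats::fft(grid$data) * filt, inverse = TRUE)) /
    length(grid$data)
  voxel_grid(out, grid$voxel_size, grid$origin)
}

#' @rdname low_pass
#' @param image 2D numeric matrix (a projection or particle image).
#' @param voxel_size pixel size in Angstrom.
#' @export
low_pass_image <- function(image, voxel_size, resolution) {
  if (resolution < 2 * voxel_size)
    stop("resolution below Nyquist", call. = FALSE)
  filt <- fourier_filter_nd(dim(image), voxel_size, resolution)
  Re(stats::fft(stats::fft(image) * filt, inverse = TRUE)) / length(image)
}

# Radial cosine-edge Fourier mask for an n-D grid (2D or 3D): unity in the
# passband, a cosine ramp over the two Fourier shells below the cutoff
# frequency 1/resolution (shell spacing 1/(n * voxel)), zero at and beyond
# the cutoff, so out-of-band power is fully removed.
fourier_filter_nd <- function(dm, voxel_size, resolution) {
  freq_axis <- function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    k / (n * voxel_size)
  }
  axes <- lapply(dm, freq_axis)
  f2 <- Reduce(function(a, b) outer(a, b, "+"), lapply(axes, function(a) a^2))
  f <- sqrt(array(f2, dim = dm))
  fc <- 1 / resolution
  w <- min(2 / (min(dm) * voxel_size), 0.9 * fc)  # two shells, kept below DC
  h <- array(0, dim = dm)
  h[f <= fc - w] <- 1
  ramp <- f > fc - w & f < fc
  h[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - (fc - w)) / w))
  h
}

#' Normalise a map to zero mean, unit standard deviation
#'
#' @param grid a non-constant [voxel_grid()].
#' @return A [voxel_grid()] whose voxel values have mean 0 and sd 1.
#' @export
normalize_map <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  s <- stats::sd(grid$data)
  if (!is.finite(s) || s == 0)
    stop("cannot normalise a constant map (zero variance)", call. = FALSE)
  voxel_grid((grid$data - mean(grid$data)) / s, grid$voxel_size, grid$origin)
}
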