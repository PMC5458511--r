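#' Voxel grid: a 3D scalar density map
#'
#' The basic container used throughout volscape: a 3D numeric array of
#' density values together with an isotropic voxel size (Angstrom per voxel)
#' and the position of voxel (1,1,1) in Angstrom (`origin`). Class volumes,
#' eigenvolumes and reconstructions are all `voxel_grid` objects.
#'
#' @param data 3D numeric array; each dimension must be at least 8.
#' @param voxel_size isotropic voxel size in Angstrom (> 0).
#' @param origin numeric length-3, Angstrom offset of the first voxel.
#' @return An object of class `voxel_grid` with fields `data`, `voxel_size`,
#'   `origin` and `shape`.
#' @examples
#' g <- voxel_grid(array(0, c(8, 8, 8)), voxel_size = 4)
#' g$shape
#' @export
voxel_grid <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 8L))
    stop("grid dimensions must all be >= 8 voxels", call. = FALSE)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (Angstrom)", call. = FALSE)
  if (length(origin) != 3L || !is.numeric(origin))
    stop("`origin` must be a numeric 3-vector", call. = FALSE)
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin), shape = dim(data)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.4g A/voxel\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size))
  cat(sprintf("  origin (A): %.3g %.3g %.3g\n", x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density: min %.4g, max %.4g, mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Binary mask on a voxel grid
#'
#' A region selector sharing the shape/voxel size contract of its parent
#' grid. Stored internally as a logical array; on disk masks are 0/1 float
#' MRC maps.
#'
#' @param data 3D logical (or 0/1 numeric) array with at least one `TRUE` voxel.
#' @param voxel_size,origin as in [voxel_grid()].
#' @return An object of class `binary_mask` (which also inherits `voxel_grid`).
#' @export
binary_mask <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (is.numeric(data)) {
    storage <- array(data > 0.5, dim = dim(data))
  } else storage <- data
  if (!is.logical(storage)) stop("mask data must be logical or 0/1 numeric", call. = FALSE)
  if (!any(storage)) stop("mask must contain at least one TRUE voxel", call. = FALSE)
  g <- voxel_grid(array(as.logical(storage), dim = dim(data)), voxel_size, origin)
  class(g) <- c("binary_mask", "voxel_grid")
  g
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d x %d voxels, %.4g A/voxel, %d voxels set\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size, sum(x$data)))
  invisible(x)
}

#' Combine compatible masks
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return The voxel-wise AND / OR as a `binary_mask`.
#' @export
mask_and <- function(a, b) {
  check_same_grid(a, b)
  binary_mask(a$data & b$data, a$voxel_size, a$origin)
}

#' @rdname mask_and
#' @export
mask_or <- function(a, b) {
  check_same_grid(a, b)
  binary_mask(a$data | b$data, a$voxel_size, a$origin)
}

# Error unless two grids share shape and voxel size (1e-4 A tolerance).
check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  if (!identical(a$shape, b$shape))
    stop("grids have different shapes: ", paste(a$shape, collapse = "x"),
         " vs ", paste(b$shape, collapse = "x"), call. = FALSE)
  if (abs(a$voxel_size - b$voxel_size) > 1e-4)
    stop("grids have different voxel sizes", call. = FALSE)
  invisible(TRUE)
}

# Voxel-centre coordinates (Angstrom, relative to box centre) along one axis.
axis_coords <- function(n, voxel_size) {
  (seq_len(n) - (n + 1) / 2) * voxel_size
}
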