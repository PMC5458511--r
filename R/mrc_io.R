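#' Read an MRC/CCP4 density map
#'
#' Reads a map in the MRC2014 dialect into a [voxel_grid()]. Modes 0 (int8),
#' 1 (int16) and 2 (float32) are supported; extended headers are skipped.
#' The density is returned untouched (no normalisation). Axis order must be
#' the standard x-fastest (MAPC,MAPR,MAPS = 1,2,3).
#'
#' @param path path to an MRC/CCP4 file.
#' @return A [voxel_grid()].
#' @seealso [write_map()], [read_mask()]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file does not exist: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  if (length(hdr_ints) < 256)
    stop("truncated MRC header in: ", path, call. = FALSE)
  # re-read words that are IEEE floats
  seek(con, 0)
  hdr_raw <- readBin(con, "raw", n = 1024)
  fword <- function(i) readBin(hdr_raw[(4 * (i - 1) + 1):(4 * i)], "numeric",
                               size = 4, endian = "little")
  nx <- hdr_ints[1]; ny <- hdr_ints[2]; nz <- hdr_ints[3]
  mode <- hdr_ints[4]
  mx <- hdr_ints[8]; my <- hdr_ints[9]; mz <- hdr_ints[10]
  cella <- c(fword(11), fword(12), fword(13))
  mapcrs <- hdr_ints[17:19]
  nsymbt <- hdr_ints[24]
  origin <- c(fword(50), fword(51), fword(52))
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 4096))
    stop("implausible MRC dimensions in: ", path, call. = FALSE)
  if (!identical(mapcrs, c(1L, 2L, 3L)))
    stop("unsupported MRC axis order (MAPC,MAPR,MAPS != 1,2,3) in: ", path, call. = FALSE)
  vs <- cella / c(mx, my, mz)
  if (any(!is.finite(vs)) || any(vs <= 0))
    stop("invalid cell dimensions in: ", path, call. = FALSE)
  if ((max(vs) - min(vs)) / mean(vs) > 0.01)
    stop("anisotropic voxel size (> 1% spread) is unsupported: ", path, call. = FALSE)
  n <- as.double(nx) * ny * nz
  seek(con, 1024 + nsymbt)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    stop("unsupported MRC mode ", mode, " in: ", path, call. = FALSE))
  if (length(vals) < n)
    stop("truncated MRC data block in: ", path, call. = FALSE)
  voxel_grid(array(vals, dim = c(nx, ny, nz)), voxel_size = mean(vs),
             origin = origin)
}

#' Write a voxel grid as an MRC map
#'
#' Writes MRC2014 mode 2 (float32), x-fastest, with the cell set to
#' shape x voxel size and the grid origin stored in the ORIGIN header words.
#'
#' @param grid a [voxel_grid()] (a [binary_mask()] is written as 0/1 floats).
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  dirn <- dirname(path)
  if (!dir.exists(dirn)) stop("directory does not exist: ", dirn, call. = FALSE)
  dat <- grid$data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim = dim(dat))
  dm <- dim(dat)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dm)                                   # NX NY NZ
  wi(2L)                                   # MODE 2 = float32
  wi(c(0L, 0L, 0L))                        # NXSTART..
  wi(dm)                                   # MX MY MZ
  wf(dm * grid$voxel_size)                 # CELLA
  wf(c(90, 90, 90))                        # CELLB
  wi(c(1L, 2L, 3L))                        # MAPC MAPR MAPS
  wf(c(min(dat), max(dat), mean(dat)))     # DMIN DMAX DMEAN
  wi(1L)                                   # ISPG
  wi(0L)                                   # NSYMBT
  wi(rep(0L, 25))                          # EXTRA (words 26-49)
  wf(grid$origin)                          # ORIGIN x y z (words 50-52)
  writeBin(charToRaw("MAP "), con)         # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(dat))                       # RMS
  wi(0L)                                   # NLABL
  writeBin(raw(800), con)                  # labels
  wf(as.numeric(dat))
  invisible(path)
}

#' Read a 0/1 MRC map as a binary mask
#'
#' @param path path to a mask map; voxels > 0.5 become `TRUE`.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  g <- read_map(path)
  binary_mask(g$data > 0.5, g$voxel_size, g$origin)
}

#' Write or read a 2D particle image stack
#'
#' Particle images are stored as a multi-section MRC file (nz = number of
#' particles). In R a stack is a 3D array `box x box x n`.
#'
#' @param stack 3D numeric array (x, y, particle).
#' @param voxel_size pixel size in Angstrom.
#' @param path file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns a
#'   list with `data` (3D array) and `voxel_size`.
#' @export
write_stack <- function(stack, voxel_size, path) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  g <- voxel_grid(stack, voxel_size)
  write_map(g, path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  g <- read_map(path)
  list(data = g$data, voxel_size = g$voxel_size)
}
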