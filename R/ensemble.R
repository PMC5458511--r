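#' Generate a synthetic class-volume ensemble with Boltzmann populations
#'
#' Emulates the outcome of exhaustive 3D classification of a two-body
#' complex: `n_classes` conformations on an even rotation-angle grid over
#' the energy function's domain, each rendered as a density map, with the
#' `total_particles` particles distributed over classes by a multinomial
#' draw with probabilities proportional to exp(-E(theta_i)). Inverting the
#' counts through Boltzmann's law recovers E up to an additive constant.
#'
#' @param spec a [phantom_spec()].
#' @param efun an [energy_function()].
#' @param n_classes number of conformational classes (>= 2).
#' @param total_particles total particle budget (>= n_classes).
#' @param seed integer seed for the multinomial draw.
#' @return An object of class `class_ensemble`: list with `class_thetas`
#'   (degrees), `volumes` (list of [voxel_grid()]), `counts` (integer),
#'   `manifest` (tibble), and `truth` (the specs used).
#' @export
make_class_ensemble <- function(spec, efun, n_classes, total_particles,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(efun, "energy_function"),
            n_classes >= 2, total_particles >= n_classes)
  thetas <- seq(efun$domain[1], efun$domain[2], length.out = n_classes)
  e <- efun$fn(thetas)
  p <- exp(-(e - min(e)))
  if (!any(p > 0) || sum(p) == 0)
    stop("all Boltzmann weights underflow; rescale the energy function",
         call. = FALSE)
  p <- p / sum(p)
  set.seed(seed)
  counts <- as.integer(stats::rmultinom(1, total_particles, p)[, 1])
  volumes <- lapply(thetas, function(th) render_phantom(spec, th))
  manifest <- tibble::tibble(
    class_id = seq_len(n_classes),
    theta_true = thetas,
    energy_true = e - min(e),
    n_particles = counts
  )
  structure(
    list(class_thetas = thetas, volumes = volumes, counts = counts,
         manifest = manifest,
         truth = list(phantom = spec, energy = efun, seed = seed,
                      total_particles = total_particles)),
    class = "class_ensemble"
  )
}

#' @export
print.class_ensemble <- function(x, ...) {
  cat(sprintf("<class_ensemble> %d classes, %d particles, theta [%g, %g] deg\n",
              length(x$counts), sum(x$counts),
              min(x$class_thetas), max(x$class_thetas)))
  invisible(x)
}

#' Write a class ensemble as MRC maps plus a TSV manifest
#'
#' @param ensemble a `class_ensemble`.
#' @param dir output directory (created if missing).
#' @return The manifest tibble (columns `class_id`, `map_path`,
#'   `n_particles`, `theta_true`), also written to `manifest.tsv`.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "class_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("class_%03d.mrc", seq_along(ensemble$volumes)))
  for (i in seq_along(paths)) write_map(ensemble$volumes[[i]], paths[i])
  manifest <- dplyr::mutate(ensemble$manifest, map_path = paths,
                            .after = "class_id")
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}

#' Read a class-ensemble manifest
#'
#' @param path a `manifest.tsv` written by [write_ensemble()] (or any TSV
#'   with columns `class_id`, `map_path`, `n_particles`).
#' @return A tibble; relative `map_path`s are resolved against the
#'   manifest's directory.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("class_id", "map_path", "n_particles")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  abs <- file.path(dirname(path), m$map_path)
  m$map_path <- ifelse(file.exists(m$map_path), m$map_path, abs)
  m
}
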