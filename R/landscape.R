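#' Boltzmann free-energy landscape from coefficients and particle counts
#'
#' Bins the classes on a 2D grid over a chosen pair of eigenvolume
#' coefficients; each class deposits its full particle count at its
#' coefficient point. Occupancy is optionally smoothed with a Gaussian
#' kernel (before the logarithm), and free energy follows Boltzmann's law,
#'
#'   E_b = -ln( n_b / n_max )   (units k_BT),
#'
#' so the maximum-occupancy bin defines the zero of energy and all defined
#' energies are non-negative. Empty bins are `NaN`, or capped at the
#' maximum defined energy + 1 when `cap_empty = TRUE`.
#'
#' @param coefficients N x K numeric matrix (or the `coefficients_tbl` /
#'   an `eigen_decomposition`, from which the matrix is taken).
#' @param counts integer vector of per-class particle counts (non-negative,
#'   at least one positive). Taken from the tibble's `n_particles` when
#'   `coefficients` carries it and `counts` is missing.
#' @param components integer pair: which coefficient columns span the map.
#' @param bins integer pair of bin counts, or `"auto"` (32 x 32).
#' @param smoothing_sigma Gaussian kernel width in bins (0 = none).
#' @param cap_empty replace empty-bin `NaN` by max defined energy + 1.
#' @param temperature_kelvin if non-`NULL`, energies are also reported in
#'   kJ/mol at this temperature (`energy_kj_mol` field).
#' @return An object of class `energy_landscape`: `occupancy` (integer
#'   grid), `occupancy_smoothed`, `energy` (k_BT), `axes` (components,
#'   edges, mids), `smoothing_sigma`, `class_bins` (tibble mapping each
#'   class to its bin), `total_count`.
#' @export
build_landscape <- function(coefficients, counts = NULL, components = c(1, 2),
                            bins = "auto", smoothing_sigma = 1,
                            cap_empty = FALSE, temperature_kelvin = NULL) {
  if (inherits(coefficients, "eigen_decomposition")) {
    if (is.null(counts)) counts <- coefficients$coefficients_tbl$n_particles
    coefficients <- coefficients$coefficients
  } else if (is.data.frame(coefficients)) {
    if (is.null(counts) && "n_particles" %in% names(coefficients))
      counts <- coefficients$n_particles
    coefficients <- as.matrix(dplyr::select(coefficients,
                                            dplyr::starts_with("c")))
  }
  coefficients <- as.matrix(coefficients)
  if (is.null(counts)) stop("`counts` is required", call. = FALSE)
  if (length(counts) != nrow(coefficients))
    stop("`counts` must have one entry per class", call. = FALSE)
  if (any(counts < 0) || !any(counts > 0))
    stop("counts must be non-negative with at least one positive",
         call. = FALSE)
  if (length(components) != 2 || components[1] == components[2] ||
      any(components < 1) || any(components > ncol(coefficients)))
    stop("`components` must be two distinct coefficient columns",
         call. = FALSE)
  if (identical(bins, "auto")) bins <- c(32L, 32L)
  xy <- coefficients[, components, drop = FALSE]
  edges <- lapply(1:2, function(d) {
    r <- range(xy[, d])
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)      # single point: unit box
    m <- 0.05 * diff(r)                          # 5% margin
    seq(r[1] - m, r[2] + m, length.out = bins[d] + 1)
  })
  bx <- findInterval(xy[, 1], edges[[1]], rightmost.closed = TRUE,
                     all.inside = TRUE)
  by <- findInterval(xy[, 2], edges[[2]], rightmost.closed = TRUE,
                     all.inside = TRUE)
  occ <- matrix(0, bins[1], bins[2])
  for (i in seq_along(counts)) occ[bx[i], by[i]] <- occ[bx[i], by[i]] + counts[i]
  occ_s <- if (smoothing_sigma > 0) gauss_smooth2(occ, smoothing_sigma) else occ
  energy <- -log(occ_s / max(occ_s))
  energy[occ_s == 0] <- NaN
  if (cap_empty) {
    cap <- max(energy[is.finite(energy)]) + 1
    energy[!is.finite(energy)] <- cap
  }
  out <- structure(
    list(occupancy = occ, occupancy_smoothed = occ_s, energy = energy,
         axes = list(components = components, edges = edges,
                     mids = lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)),
         smoothing_sigma = smoothing_sigma, cap_empty = cap_empty,
         class_bins = tibble::tibble(class_id = seq_along(counts),
                                     bin_x = bx, bin_y = by,
                                     count = as.integer(counts)),
         total_count = sum(counts)),
    class = "energy_landscape"
  )
  if (!is.null(temperature_kelvin))
    out$energy_kj_mol <- energy * 8.314462618e-3 * temperature_kelvin
  out
}

# Separable Gaussian smoothing with kernel truncated at 4 sigma,
# renormalised at the borders (no occupancy mass is lost).
gauss_smooth2 <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    wsum <- numeric(n)
    for (d in -r:r) {
      src <- seq_len(n) + d
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[d + r + 1] * mat[src[ok], ]
      wsum[ok] <- wsum[ok] + k[d + r + 1]
    }
    out / wsum
  }
  t(smooth1(t(smooth1(m))))
}

#' @export
print.energy_landscape <- function(x, ...) {
  nf <- sum(is.finite(x$energy))
  cat(sprintf("<energy_landscape> %d x %d bins over components (%d, %d)\n",
              nrow(x$energy), ncol(x$energy),
              x$axes$components[1], x$axes$components[2]))
  cat(sprintf("  %d defined bins, %d particles, max defined energy %.2f k_BT\n",
              nf, x$total_count, max(x$energy[is.finite(x$energy)])))
  invisible(x)
}

#' @export
tidy.energy_landscape <- function(x, ...) {
  grid <- expand.grid(bin_x = seq_len(nrow(x$energy)),
                      bin_y = seq_len(ncol(x$energy)))
  tibble::tibble(
    bin_x = grid$bin_x, bin_y = grid$bin_y,
    coef_x = x$axes$mids[[1]][grid$bin_x],
    coef_y = x$axes$mids[[2]][grid$bin_y],
    occupancy = as.integer(x$occupancy[cbind(grid$bin_x, grid$bin_y)]),
    energy = x$energy[cbind(grid$bin_x, grid$bin_y)]
  )
}

#' @export
glance.energy_landscape <- function(x, ...) {
  fin <- x$energy[is.finite(x$energy)]
  tibble::tibble(bins_x = nrow(x$energy), bins_y = ncol(x$energy),
                 defined_bins = length(fin), total_count = x$total_count,
                 max_energy = max(fin), smoothing_sigma = x$smoothing_sigma)
}

#' Heat-map of an energy landscape
#'
#' @param object an `energy_landscape`.
#' @param ... unused.
#' @return A ggplot object (energy in k_BT; empty bins blank).
#' @export
autoplot.energy_landscape <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coef_x, y = .data$coef_y,
                                   fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", option = "turbo",
                                  name = expression(E ~ (k[B] * T))) +
    ggplot2::labs(x = sprintf("coefficient %d", object$axes$components[1]),
                  y = sprintf("coefficient %d", object$axes$components[2])) +
    ggplot2::theme_minimal()
}

#' Locate minima and the barrier between the two lowest minima
#'
#' Minima are local minima of the defined (finite-energy) bins over their
#' 8-neighbourhoods. The barrier between the two lowest minima is found by
#' the minimax-path criterion: bins are flooded in order of increasing
#' energy and the level at which the two minima first become 8-connected
#' is the lowest possible maximal energy along any connecting path; the
#' barrier height is that level minus the higher of the two minima. If the
#' minima lie in disconnected defined regions the barrier is infinite
#' (`disconnected = TRUE`).
#'
#' @param landscape an `energy_landscape`.
#' @return A list of class `barrier_report`: `minima` (tibble: bin_x,
#'   bin_y, energy), `barrier_height` (k_BT; `NA` if fewer than two
#'   minima, `Inf` if disconnected), `barrier_level`, `path` (tibble of
#'   bins along a minimax path), `disconnected`.
#' @export
find_minima_and_barrier <- function(landscape) {
  E <- landscape$energy
  nb1 <- nrow(E); nb2 <- ncol(E)
  defined <- which(is.finite(E), arr.ind = TRUE)
  if (nrow(defined) == 0) stop("landscape has no defined bins", call. = FALSE)
  neighbours <- function(i, j) {
    di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
    keep <- !(di == 0 & dj == 0)
    ii <- i + di[keep]; jj <- j + dj[keep]
    ok <- ii >= 1 & ii <= nb1 & jj >= 1 & jj <= nb2
    cbind(ii[ok], jj[ok])
  }
  is_min <- logical(nrow(defined))
  for (r in seq_len(nrow(defined))) {
    i <- defined[r, 1]; j <- defined[r, 2]
    nb <- neighbours(i, j)
    ev <- E[nb]
    is_min[r] <- all(!is.finite(ev) | E[i, j] <= ev)
  }
  minima <- tibble::tibble(bin_x = defined[is_min, 1],
                           bin_y = defined[is_min, 2],
                           energy = E[defined[is_min, , drop = FALSE]])
  minima <- dplyr::arrange(minima, .data$energy, .data$bin_x, .data$bin_y)
  if (nrow(minima) < 2) {
    return(structure(list(minima = minima, barrier_height = NA_real_,
                          barrier_level = NA_real_, path = NULL,
                          disconnected = FALSE),
                     class = "barrier_report"))
  }
  m1 <- c(minima$bin_x[1], minima$bin_y[1])
  m2 <- c(minima$bin_x[2], minima$bin_y[2])
  # flood bins in order of increasing energy; union-find over bins
  ord <- order(E[defined])
  parent <- seq_len(nrow(defined))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx_of <- matrix(NA_integer_, nb1, nb2)
  added <- matrix(FALSE, nb1, nb2)
  r1 <- which(defined[, 1] == m1[1] & defined[, 2] == m1[2])
  r2 <- which(defined[, 1] == m2[1] & defined[, 2] == m2[2])
  level <- NA_real_
  for (r in ord) {
    i <- defined[r, 1]; j <- defined[r, 2]
    idx_of[i, j] <- r
    added[i, j] <- TRUE
    nb <- neighbours(i, j)
    for (q in seq_len(nrow(nb))) {
      if (added[nb[q, 1], nb[q, 2]]) {
        ra <- find(r); rb <- find(idx_of[nb[q, 1], nb[q, 2]])
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (find(r1) == find(r2)) { level <- E[i, j]; break }
  }
  if (is.na(level)) {
    return(structure(list(minima = minima, barrier_height = Inf,
                          barrier_level = NA_real_, path = NULL,
                          disconnected = TRUE),
                     class = "barrier_report"))
  }
  # a minimax path: BFS through bins with E <= level
  path <- bfs_path(E, m1, m2, level)
  structure(list(minima = minima,
                 barrier_height = level - max(E[m1[1], m1[2]], E[m2[1], m2[2]]),
                 barrier_level = level, path = path, disconnected = FALSE),
            class = "barrier_report")
}

bfs_path <- function(E, from, to, level) {
  nb1 <- nrow(E); nb2 <- ncol(E)
  ok <- is.finite(E) & E <= level + 1e-12
  prev <- array(NA_integer_, dim = c(nb1, nb2, 2))
  seen <- matrix(FALSE, nb1, nb2)
  queue <- list(from); seen[from[1], from[2]] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (all(cur == to)) break
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      i <- cur[1] + di; j <- cur[2] + dj
      if (i < 1 || i > nb1 || j < 1 || j > nb2) next
      if (!ok[i, j] || seen[i, j]) next
      seen[i, j] <- TRUE
      prev[i, j, ] <- cur
      queue[[length(queue) + 1]] <- c(i, j)
    }
  }
  if (!seen[to[1], to[2]]) return(NULL)
  path <- list(to)
  cur <- to
  while (!all(cur == from)) {
    cur <- prev[cur[1], cur[2], ]
    path[[length(path) + 1]] <- cur
  }
  path <- rev(path)
  tibble::tibble(bin_x = vapply(path, `[`, integer(1), 1),
                 bin_y = vapply(path, `[`, integer(1), 2),
                 energy = vapply(path, function(p) E[p[1], p[2]], numeric(1)))
}

#' @export
print.barrier_report <- function(x, ...) {
  cat(sprintf("<barrier_report> %d minima", nrow(x$minima)))
  if (!is.na(x$barrier_height))
    cat(sprintf("; barrier %.2f k_BT%s", x$barrier_height,
                if (x$disconnected) " (disconnected)" else ""))
  cat("\n")
  invisible(x)
}

#' Compare two energy landscapes on identical binning
#'
#' Reports the bin-wise energy difference over commonly defined bins and
#' how much the occupied (defined) area contracts from `a` to `b` --- the
#' restriction of conformational space induced, e.g., by inhibitor binding.
#'
#' @param a,b `energy_landscape`s with identical axes/binning.
#' @return A list: `difference` (b - a energy grid), `summary` tibble with
#'   `max_abs_dE` over common defined bins and `occupied_area_ratio`
#'   (#defined in b / #defined in a).
#' @export
compare_landscapes <- function(a, b) {
  same <- isTRUE(all.equal(a$axes$edges, b$axes$edges)) &&
    identical(dim(a$energy), dim(b$energy))
  if (!same)
    stop("landscapes have incompatible binning; rebin onto common axes first",
         call. = FALSE)
  common <- is.finite(a$energy) & is.finite(b$energy)
  diff <- b$energy - a$energy
  diff[!common] <- NaN
  list(difference = diff,
       summary = tibble::tibble(
         max_abs_dE = if (any(common)) max(abs(diff[common])) else NA_real_,
         occupied_area_ratio = sum(is.finite(b$energy)) /
           sum(is.finite(a$energy))))
}

#' Write a landscape as TSV (long format) plus a PNG heat map
#'
#' @param landscape an `energy_landscape`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "landscape.tsv")
  readr::write_tsv(tidy(landscape), tsv)
  png <- file.path(dir, "landscape.png")
  ggplot2::ggsave(png, autoplot(landscape), width = 5, height = 4, dpi = 150)
  invisible(c(tsv, png))
}
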