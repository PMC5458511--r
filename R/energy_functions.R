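#' Energy functions over the rotation coordinate
#'
#' Defines the ground-truth free-energy profile E(theta), in units of
#' k_BT, from which synthetic class populations are drawn with
#' p_i proportional to exp(-E(theta_i)). Three shapes are available:
#'
#' * `flat` - E = 0 everywhere: an unrestricted, freely sampling complex.
#' * `harmonic` - E = kappa/2 * (theta - center)^2: a single soft minimum.
#' * `double_well_barrier` - two wells separated by a barrier, the
#'   hallmark of an inhibitor-restricted landscape. Built as a monotone
#'   Hermite spline through the well centres, the barrier top (midway
#'   between the wells) and elevated domain edges, so the well energies
#'   and the barrier height are attained exactly, with no spline overshoot.
#'
#' Energies are shifted so the minimum over the domain is 0.
#'
#' @param kind one of `"flat"`, `"harmonic"`, `"double_well_barrier"`.
#' @param domain numeric length-2, angle range in degrees.
#' @param kappa harmonic stiffness, k_BT per degree squared.
#' @param center harmonic minimum position, degrees.
#' @param well_centers numeric length-2, well positions (degrees).
#' @param well_energies numeric length-2, well energies in k_BT (>= 0).
#' @param barrier_height barrier-top energy in k_BT above 0.
#' @param edge_energy energy at the domain edges, k_BT.
#' @return An object of class `energy_function`: a list with `kind`,
#'   `domain`, `params` and a vectorised evaluator `fn(theta)`.
#' @examples
#' ef <- energy_function("double_well_barrier", domain = c(-25, 25),
#'                       well_centers = c(-15, 15), barrier_height = 3)
#' ef$fn(c(-15, 0, 15))
#' @export
energy_function <- function(kind = c("flat", "harmonic", "double_well_barrier"),
                            domain = c(-25, 25),
                            kappa = 0.02, center = 0,
                            well_centers = c(-15, 15),
                            well_energies = c(0, 0),
                            barrier_height = 3,
                            edge_energy = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(domain) == 2, domain[2] > domain[1])
  if (kind == "flat") {
    fn <- function(theta) rep(0, length(theta))
    params <- list()
  } else if (kind == "harmonic") {
    stopifnot(kappa > 0)
    base <- function(theta) kappa / 2 * (theta - center)^2
    off <- min(base(seq(domain[1], domain[2], length.out = 2001)))
    fn <- function(theta) base(theta) - off
    params <- list(kappa = kappa, center = center)
  } else {
    stopifnot(length(well_centers) == 2, well_centers[1] < well_centers[2],
              well_centers[1] > domain[1], well_centers[2] < domain[2],
              all(well_energies >= 0), barrier_height > max(well_energies))
    if (is.null(edge_energy)) edge_energy <- barrier_height + 2
    mid <- mean(well_centers)
    xs <- c(domain[1], well_centers[1], mid, well_centers[2], domain[2])
    ys <- c(edge_energy, well_energies[1], barrier_height,
            well_energies[2], edge_energy) - min(well_energies)
    # piecewise-cosine interpolation: C1, attains every anchor exactly,
    # monotone within each segment (no spline overshoot)
    fn <- function(theta) {
      th <- pmin(pmax(theta, domain[1]), domain[2])
      seg <- findInterval(th, xs, rightmost.closed = TRUE, all.inside = TRUE)
      t <- (th - xs[seg]) / (xs[seg + 1] - xs[seg])
      ys[seg] + (ys[seg + 1] - ys[seg]) * (1 - cos(pi * t)) / 2
    }
    params <- list(well_centers = well_centers, well_energies = well_energies,
                   barrier_height = barrier_height, edge_energy = edge_energy)
  }
  ev <- fn(seq(domain[1], domain[2], length.out = 2001))
  if (any(!is.finite(ev))) stop("energy function not finite on domain", call. = FALSE)
  structure(list(kind = kind, domain = domain, params = params, fn = fn),
            class = "energy_function")
}

#' @export
print.energy_function <- function(x, ...) {
  cat(sprintf("<energy_function> %s on [%g, %g] deg\n",
              x$kind, x$domain[1], x$domain[2]))
  if (length(x$params))
    cat("  ", paste(names(x$params),
                    vapply(x$params, function(p) paste(signif(p, 4), collapse = ","),
                           ""), sep = "=", collapse = "  "), "\n")
  invisible(x)
}
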