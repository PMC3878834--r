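#' Probability that a motility attempt succeeds under adhesion
#'
#' An agent selected for a motility event moves with probability
#' `p_m * (1 - q)^a`, where `a` is the number of its four von Neumann
#' neighbour sites that are occupied. With `q = 0` adhesion plays no role;
#' with `q = 1` any contact blocks movement entirely.
#'
#' @param p_m Probability that an isolated agent moves one lattice spacing
#'   during one time step, in `[0, 1]`.
#' @param q Cell-to-cell adhesion strength, in `[0, 1]`.
#' @param a Number of occupied von Neumann neighbours, an integer in `0:4`.
#' @return The attempt probability, a numeric in `[0, p_m]`. Vectorised over
#'   all arguments.
#' @examples
#' motility_probability(1, 0.5, 2) # 0.25
#' @export
motility_probability <- function(p_m, q, a) {
  stopifnot(all(p_m >= 0 & p_m <= 1), all(q >= 0 & q <= 1))
  if (any(a != floor(a)) || any(a < 0) || any(a > 4)) {
    stop("`a` must be an integer count of von Neumann neighbours in 0:4")
  }
  p_m * (1 - q)^a
}

#' Cell diffusivity implied by the lattice step parameters
#'
#' The macroscopic cell diffusivity of an unbiased nearest-neighbour random
#' walk on a square lattice is `D = p_m * delta^2 / (4 * tau)`.
#'
#' @param p_m Motility probability per step, in `[0, 1]`.
#' @param delta Lattice spacing, micrometres.
#' @param tau Step duration, hours. Must be positive.
#' @return Diffusivity in square micrometres per hour.
#' @examples
#' diffusivity(1, 18, 1) # 81
#' @export
diffusivity <- function(p_m, delta = 18, tau = 1) {
  if (any(tau <= 0)) stop("`tau` must be a positive step duration")
  p_m * delta^2 / (4 * tau)
}

#' Proliferation rate implied by the per-step probability
#'
#' @param p_p Proliferation probability per step, in `[0, 1]`.
#' @param tau Step duration, hours. Must be positive.
#' @return Rate in per hour, `p_p / tau`.
#' @export
proliferation_rate <- function(p_p, tau = 1) {
  if (any(tau <= 0)) stop("`tau` must be a positive step duration")
  p_p / tau
}

#' Population doubling time of exponential growth
#'
#' @param lambda Proliferation rate, per hour. Must be positive.
#' @return Doubling time `log(2) / lambda`, hours.
#' @examples
#' doubling_time(0.0305) # about 22.7 hours
#' @export
doubling_time <- function(lambda) {
  if (any(lambda <= 0)) stop("doubling time is undefined for `lambda` <= 0")
  log(2) / lambda
}

#' Lattice sites per side for a culture well
#'
#' @param well_diameter Well diameter, micrometres.
#' @param delta Lattice spacing, micrometres.
#' @return Number of lattice sites per side, `round(well_diameter / delta)`.
#' @examples
#' lattice_dimension(15600, 18) # 867
#' @export
lattice_dimension <- function(well_diameter, delta = 18) {
  stopifnot(well_diameter > 0, delta > 0)
  as.integer(round(well_diameter / delta))
}

#' Percentage of disc sites occupied by an initial cell number
#'
#' @param n_cells Number of cells placed in the initial disc.
#' @param n_sites Number of lattice sites inside the disc.
#' @return Occupancy percentage, `100 * n_cells / n_sites`.
#' @export
occupancy_percentage <- function(n_cells, n_sites) {
  stopifnot(n_sites > 0, n_cells >= 0)
  100 * n_cells / n_sites
}

#' Lattice model parameters from macroscopic rates
#'
#' Converts a target cell diffusivity `D` (square micrometres per hour) and
#' proliferation rate `lambda` (per hour) into per-step lattice parameters.
#' For `D >= delta^2 / 4` the motility probability is pinned at `p_m = 1`
#' and the step duration shrinks, `tau = delta^2 / (4 D)`; for smaller `D`
#' the step stays at one hour and `p_m = 4 D tau / delta^2 < 1`. The step
#' count `b = duration / tau` is forced to an integer (with `tau` and `p_m`
#' re-adjusted so both `b * tau = duration` and the implied diffusivity
#' equal their targets exactly).
#'
#' @param D Cell diffusivity, square micrometres per hour (non-negative).
#' @param q Cell-to-cell adhesion strength in `[0, 1]`.
#' @param lambda Proliferation rate, per hour (non-negative).
#' @param delta Lattice spacing, micrometres.
#' @param duration Total simulated time, hours.
#' @param lattice_dim Lattice sites per side.
#' @param tau Optional step duration override, hours; useful for checking
#'   that results are insensitive to the temporal discretisation (the
#'   default picks the largest feasible step).
#' @return An object of class `lattice_params`: a list with elements `p_m`,
#'   `q`, `p_p`, `tau`, `delta`, `lattice_dim`, `duration`, `b`, and the
#'   derived `D` and `lambda`.
#' @examples
#' lattice_params(810, 0, 0)$b # 480 steps over 48 hours
#' @export
lattice_params <- function(D, q = 0, lambda = 0, delta = 18, duration = 48,
                           lattice_dim = 867L, tau = NULL) {
  stopifnot(D >= 0, lambda >= 0, q >= 0, q <= 1, delta > 0, duration > 0)
  if (!is.null(tau)) {
    tau0 <- tau
    stopifnot(tau0 > 0)
    if (4 * D * tau0 / delta^2 > 1 + 1e-12) {
      stop("the requested `tau` needs a motility probability above 1")
    }
  } else if (D <= 0) {
    tau0 <- 1
  } else if (D >= delta^2 / 4) {
    tau0 <- delta^2 / (4 * D)
  } else {
    tau0 <- 1
  }
  b <- max(1L, as.integer(round(duration / tau0)))
  repeat {
    tau <- duration / b
    p_m <- 4 * D * tau / delta^2
    if (p_m <= 1 + 1e-12) break
    b <- b + 1L
  }
  p_m <- min(p_m, 1)
  p_p <- lambda * tau
  if (p_p > 1) {
    stop("infeasible proliferation: `lambda * tau` exceeds 1; ",
         "use a larger `D` or shorter step")
  }
  structure(
    list(p_m = p_m, q = q, p_p = p_p, tau = tau, delta = delta,
         lattice_dim = as.integer(lattice_dim), duration = duration,
         b = b, D = diffusivity(p_m, delta, tau),
         lambda = proliferation_rate(p_p, tau)),
    class = "lattice_params"
  )
}

#' @export
print.lattice_params <- function(x, ...) {
  cat("<lattice_params>\n")
  cat(sprintf("  D = %g um^2/h (p_m = %g, tau = %g h, %d steps over %g h)\n",
              x$D, x$p_m, x$tau, x$b, x$duration))
  cat(sprintf("  q = %g, lambda = %g /h (p_p = %g)\n", x$q, x$lambda, x$p_p))
  cat(sprintf("  lattice %d x %d, spacing %g um\n",
              x$lattice_dim, x$lattice_dim, x$delta))
  invisible(x)
}
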