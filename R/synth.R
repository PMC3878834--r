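#' Generate a pseudo-experimental observation set
#'
#' Simulates replicate circular barrier assays at known "true" parameters
#' and applies the same extractors used during calibration, producing the
#' four data-type tables an experimental campaign would yield: leading-edge
#' radii, transect density profiles, isolated-cell clustering summaries,
#' and subregion densities. Replicate variability comes entirely from the
#' stochastic model (one seed per replicate); there is no extra measurement
#' noise.
#'
#' @param D,q,lambda True model parameters (diffusivity in square
#'   micrometres per hour, adhesion in `[0, 1]`, proliferation per hour).
#' @param n_cells Cells seeded inside the barrier.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param replicates Number of replicate assays (the assay standard is 3).
#' @param record_times Observation times, hours.
#' @param closing_radius Edge-detection closing radius, micrometres.
#' @return An `observation_set`: list of tibbles `radii` (replicate, t,
#'   area, radius), `profiles` (replicate, t, section, r_um, density),
#'   `clustering` (replicate, t, region, total, isolated, pct_isolated),
#'   `subregions` (replicate, t, box, count, density), with a `provenance`
#'   attribute recording the truth and seeds.
#' @export
generate_observation_set <- function(D, q, lambda, n_cells, seed = 1,
                                     replicates = 3,
                                     record_times = c(0, 24, 48),
                                     closing_radius = 54) {
  assay <- simulate_barrier_assay(D, q, lambda, n_cells,
                                  replicates = replicates,
                                  record_times = record_times, seed = seed)
  radii <- assay |>
    dplyr::mutate(meas = purrr::map(
      .data$pattern,
      function(p) measure_radius(p, closing_radius = closing_radius)
    )) |>
    dplyr::select("replicate", "t", "meas") |>
    tidyr::unnest("meas")
  profiles <- assay |>
    dplyr::mutate(profile = purrr::map(.data$pattern,
                                       transect_density_profile)) |>
    dplyr::select("replicate", "t", "profile") |>
    tidyr::unnest("profile")
  clustering <- assay |>
    dplyr::mutate(cl = purrr::map(.data$pattern, clustering_regions)) |>
    dplyr::select("replicate", "t", "cl") |>
    tidyr::unnest("cl")
  subregions <- assay |>
    dplyr::mutate(sr = purrr::map(.data$pattern, subregion_density)) |>
    dplyr::select("replicate", "t", "sr") |>
    tidyr::unnest("sr")
  structure(
    list(radii = radii, profiles = profiles, clustering = clustering,
         subregions = subregions),
    provenance = list(D = D, q = q, lambda = lambda, n_cells = n_cells,
                      seed = seed, replicates = replicates,
                      record_times = record_times,
                      closing_radius = closing_radius),
    class = "observation_set"
  )
}

#' @export
print.observation_set <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf(
    "<observation_set> %d replicates at D = %g, q = %g, lambda = %g (%d cells)\n",
    p$replicates, p$D, p$q, p$lambda, p$n_cells))
  cat(sprintf("  tables: radii (%d rows), profiles (%d), clustering (%d), subregions (%d)\n",
              nrow(x$radii), nrow(x$profiles), nrow(x$clustering),
              nrow(x$subregions)))
  invisible(x)
}

#' Disc mask fixture with a known analytic area
#'
#' Renders a solid disc, optionally deletes a random fraction of its
#' interior pixels (to emulate imperfect staining), and records the
#' analytic area `pi r^2` for testing edge detection.
#'
#' @param radius_um Disc radius, micrometres.
#' @param hole_fraction Fraction of disc pixels cleared at random, in
#'   `[0, 0.3)`.
#' @param pixel_um Pixel size, micrometres.
#' @param seed Seed for the hole placement.
#' @param dim Mask side length in pixels; default fits the disc with a
#'   margin.
#' @return A `binary_mask` with attribute `true_area` (square micrometres).
#' @export
generate_mask_fixture <- function(radius_um, hole_fraction = 0,
                                  pixel_um = 18, seed = 1, dim = NULL) {
  stopifnot(hole_fraction >= 0, hole_fraction < 0.3)
  dim <- dim %||% (2L * as.integer(ceiling(radius_um / pixel_um)) + 11L)
  ctr <- (dim - 1) / 2
  xs <- (seq_len(dim) - 1 - ctr) * pixel_um
  d2 <- outer(xs^2, xs^2, `+`) # rows = y, cols = x
  m <- if (radius_um > 0) (d2 <= radius_um^2) * 1L else d2 * 0L
  if (hole_fraction > 0 && any(m == 1)) {
    set.seed(seed)
    inside <- which(m == 1L)
    holes <- sample(inside, round(hole_fraction * length(inside)))
    m[holes] <- 0L
  }
  out <- binary_mask(m, pixel_um)
  attr(out, "true_area") <- pi * radius_um^2
  out
}

#' Noisy logistic growth density table
#'
#' Evaluates the logistic growth solution at the requested times and
#' perturbs each replicate value with mean-zero multiplicative noise of the
#' given coefficient of variation, truncating to `[0, 1]`.
#'
#' @param c0 Initial density in `(0, 1)`.
#' @param lambda Proliferation rate, per hour.
#' @param times Observation times, hours.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param replicates Number of replicates per time.
#' @param seed Seed.
#' @return Tibble with `replicate`, `t`, `density`.
#' @export
generate_logistic_counts <- function(c0, lambda, times = c(0, 24, 48),
                                     noise_cv = 0, replicates = 4,
                                     seed = 1) {
  stopifnot(c0 > 0, c0 < 1, noise_cv >= 0)
  set.seed(seed)
  truth <- logistic_solution(c0, lambda, times)
  out <- tidyr::expand_grid(replicate = seq_len(replicates), t = times)
  out$density <- rep(truth, times = replicates)
  if (noise_cv > 0) {
    eps <- stats::rnorm(nrow(out), 0, noise_cv)
    out$density <- pmin(1, pmax(0, out$density * (1 + eps)))
  }
  out
}
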