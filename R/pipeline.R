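#' Two-stage calibration of a barrier-assay observation set
#'
#' Reproduces the estimation logic of the assay analysis: the clustering
#' error surface identifies the adhesion strength `q` (the leading-edge and
#' profile surfaces do not), and the leading-edge surface, read at the
#' estimated `q`, then yields the admissible diffusivity range and a point
#' estimate of `D`.
#'
#' @param observations An `observation_set` from a non-proliferative
#'   (proliferation-suppressed) experiment.
#' @param D_grid,q_grid Calibration grids; the defaults are a reduced
#'   10 x 6 grid suitable for routine runs (the full assay analysis used
#'   denser grids).
#' @param replicates Named overrides of the per-data-type replicate counts,
#'   e.g. `c(clustering = 5)`.
#' @param tolerance_factor Error multiple used when reading intervals off
#'   surfaces.
#' @param seed Base seed for the sweeps.
#' @param surfaces Which surfaces to compute; the clustering and
#'   leading-edge surfaces are required for the estimates.
#' @return A `colony_calibration` object: list with `q_estimate`,
#'   `D_estimate`, and the computed `surfaces`.
#' @export
calibrate_colony <- function(observations,
                             D_grid = 81 * 1:10,
                             q_grid = seq(0, 1, by = 0.2),
                             replicates = NULL,
                             tolerance_factor = 2, seed = 1,
                             surfaces = c("clustering", "leading_edge")) {
  reps <- default_replicates
  if (!is.null(replicates)) reps[names(replicates)] <- replicates
  surf <- list()
  for (s in surfaces) {
    surf[[s]] <- sweep_error_surface(observations, s, D_grid, q_grid,
                                     replicates = reps[[s]],
                                     seed = seed + match(s, surfaces))
  }
  if (is.null(surf$clustering) || is.null(surf$leading_edge)) {
    stop("calibration needs both the clustering and leading-edge surfaces")
  }
  q_est <- estimate_q(surf$clustering, tolerance_factor)
  q_mid <- q_grid[which.min(abs(q_grid - (q_est$q_low + q_est$q_high) / 2))]
  # one-pixel detection resolution: radius mismatches below one lattice
  # spacing are not distinguishable, whatever the sampled surface minimum
  le_floor <- (18 / mean(observations$radii$radius))^2
  D_est <- conditional_D_range(surf$leading_edge, q_mid, tolerance_factor,
                               resolution = le_floor)
  structure(list(q_estimate = q_est, D_estimate = D_est, surfaces = surf,
                 tolerance_factor = tolerance_factor),
            class = "colony_calibration")
}

#' @export
print.colony_calibration <- function(x, ...) {
  cat("<colony_calibration>\n")
  cat(sprintf("  q in [%g, %g] (marginal arg-min %g; q/D variation ratio %.3g)\n",
              x$q_estimate$q_low, x$q_estimate$q_high, x$q_estimate$q_hat,
              x$q_estimate$q_to_D_variation))
  cat(sprintf("  D in [%g, %g] um^2/h at q = %g (arg-min %g)\n",
              x$D_estimate$D_low, x$D_estimate$D_high, x$D_estimate$q,
              x$D_estimate$D_hat))
  invisible(x)
}

#' Predict colony expansion from fitted parameters and compare
#'
#' Simulates the assay forward at fitted `(D, q, lambda)` (three replicates
#' for radii, five for profiles) and reports the normalised errors against
#' the observed radii and density profiles.
#'
#' @param D,q,lambda Fitted parameters.
#' @param observations An `observation_set` to compare against.
#' @param seed Base seed.
#' @param times Comparison times, hours.
#' @return An `expansion_prediction`: list with `radius_comparison` and
#'   `profile_comparison` tibbles and scalar `radius_error`,
#'   `profile_error`.
#' @export
predict_expansion <- function(D, q, lambda, observations, seed = 1,
                              times = c(24, 48)) {
  n_cells <- attr(observations, "provenance")$n_cells
  sim_r <- simulate_barrier_assay(D, q, lambda, n_cells, replicates = 3,
                                  record_times = times, seed = seed)
  sim_p <- simulate_barrier_assay(D, q, lambda, n_cells, replicates = 5,
                                  record_times = times, seed = seed + 100)
  obs_r <- observed_summary(observations, "leading_edge", times)
  sim_le <- extract_le_summary(sim_r)
  obs_p <- observed_summary(observations, "density_profile", times)
  sim_dp <- extract_dp_summary(sim_p)
  radius_cmp <- tibble::tibble(t = times, observed = obs_r,
                               predicted = sim_le$value)
  profile_cmp <- sim_dp |>
    dplyr::rename(predicted = "value") |>
    dplyr::mutate(observed = obs_p)
  structure(
    list(radius_comparison = radius_cmp,
         profile_comparison = profile_cmp,
         radius_error = normalised_error(obs_r, sim_le$value),
         profile_error = normalised_error(obs_p, sim_dp$value),
         params = list(D = D, q = q, lambda = lambda)),
    class = "expansion_prediction"
  )
}

#' @export
print.expansion_prediction <- function(x, ...) {
  cat(sprintf(
    "<expansion_prediction> D = %g, q = %g, lambda = %g\n",
    x$params$D, x$params$q, x$params$lambda))
  cat(sprintf("  radius error %.4g, profile error %.4g\n",
              x$radius_error, x$profile_error))
  invisible(x)
}

#' Write an observation set to a directory of CSV tables
#'
#' Writes one tidy CSV per data type plus a `manifest.json` carrying the
#' provenance (true parameters and seeds), sufficient to regenerate every
#' table exactly.
#'
#' @param observations An `observation_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_observation_set <- function(observations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("radii", "profiles", "clustering", "subregions")
  for (tab in tables) {
    utils::write.csv(observations[[tab]],
                     file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(provenance = attr(observations, "provenance"),
         tables = paste0(tables, ".csv")),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Read an observation set written by [write_observation_set()]
#'
#' @param dir Directory containing the CSV tables and `manifest.json`.
#' @return An `observation_set`.
#' @export
read_observation_set <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  tabs <- lapply(c(radii = "radii", profiles = "profiles",
                   clustering = "clustering", subregions = "subregions"),
                 function(tab) {
                   tibble::as_tibble(
                     utils::read.csv(file.path(dir, paste0(tab, ".csv"))))
                 })
  structure(tabs, provenance = man$provenance, class = "observation_set")
}

#' Export simulated agent coordinates as CSV snapshots
#'
#' One file per replicate per recorded time, columns `x_um,y_um` measured
#' from the lattice centre.
#'
#' @param assay A tibble from [simulate_barrier_assay()].
#' @param dir Output directory.
#' @return Tibble of written files, invisibly.
#' @export
write_snapshots <- function(assay, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::pmap_chr(
    list(assay$replicate, assay$t, assay$pattern),
    function(r, t, p) {
      f <- file.path(dir, sprintf("snapshot_rep%d_t%g.csv", r, t))
      utils::write.csv(p[, c("x_um", "y_um")], f, row.names = FALSE)
      f
    })
  invisible(tibble::tibble(replicate = assay$replicate, t = assay$t,
                           file = files))
}
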