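#' Default replicate counts per data type
#'
#' Three simulated replicates for leading-edge radii, five for density
#' profiles, twenty for the clustering statistic.
#' @keywords internal
default_replicates <- c(leading_edge = 3L, density_profile = 5L,
                        clustering = 20L)

extract_le_summary <- function(assay, closing_radius = 54) {
  assay |>
    dplyr::mutate(radius = purrr::map_dbl(
      .data$pattern,
      function(p) measure_radius(p, closing_radius = closing_radius)$radius
    )) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(value = mean(.data$radius), sd = sd(.data$radius),
                     .groups = "drop")
}

extract_dp_summary <- function(assay) {
  assay |>
    dplyr::mutate(profile = purrr::map(.data$pattern,
                                       transect_density_profile)) |>
    dplyr::select("replicate", "t", "profile") |>
    tidyr::unnest("profile") |>
    dplyr::group_by(.data$t, .data$section) |>
    dplyr::summarise(value = mean(.data$density), .groups = "drop")
}

extract_cl_summary <- function(assay) {
  assay |>
    dplyr::mutate(prop = purrr::map_dbl(.data$pattern, function(p) {
      attr(clustering_regions(p), "mean_pct") / 100
    })) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(value = mean(.data$prop), sd = sd(.data$prop),
                     .groups = "drop")
}

#' Sweep an error surface over a (D, q) grid
#'
#' For each grid combination of cell diffusivity `D` and adhesion strength
#' `q`, simulates replicate non-proliferative barrier assays, extracts the
#' chosen summary statistic with exactly the extractor applied to the
#' observations, averages over replicates, and evaluates the matching
#' normalised least-squares error against the observations at the two
#' post-seeding time points.
#'
#' @param observations An `observation_set` (see
#'   [generate_observation_set()]), or a list with the component required by
#'   `data_type` (`radii`, `profiles`, or `clustering`).
#' @param data_type `"leading_edge"`, `"density_profile"`, or
#'   `"clustering"`.
#' @param D_grid Diffusivity grid, square micrometres per hour (strictly
#'   increasing; multiples of `delta^2/4` keep the step count integral with
#'   `p_m = 1`).
#' @param q_grid Adhesion grid in `[0, 1]` (strictly increasing).
#' @param replicates Simulated replicates per grid cell; defaults to the
#'   data type's standard count (3, 5 or 20).
#' @param n_cells Cells seeded per assay; defaults to the observation set's
#'   provenance.
#' @param seed Base seed; cell `(i, j)`, replicate `r` uses a distinct
#'   derived seed.
#' @param times The two comparison times, hours.
#' @return An `error_surface` tibble with columns `D`, `q`, `error`,
#'   `replicates` and attributes `data_type`, `times`, `seed`.
#' @export
sweep_error_surface <- function(observations,
                                data_type = c("leading_edge",
                                              "density_profile",
                                              "clustering"),
                                D_grid, q_grid, replicates = NULL,
                                n_cells = NULL, seed = 1,
                                times = c(24, 48)) {
  data_type <- match.arg(data_type)
  stopifnot(length(D_grid) >= 1, length(q_grid) >= 1,
            !is.unsorted(D_grid, strictly = TRUE),
            !is.unsorted(q_grid, strictly = TRUE))
  replicates <- replicates %||% default_replicates[[data_type]]
  n_cells <- n_cells %||% attr(observations, "provenance")$n_cells
  if (is.null(n_cells)) stop("`n_cells` is required")

  obs_vec <- observed_summary(observations, data_type, times)
  grid <- expand.grid(qi = seq_along(q_grid), Di = seq_along(D_grid))
  err <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    D <- D_grid[grid$Di[g]]
    q <- q_grid[grid$qi[g]]
    cell_seed <- seed + 1000L * g
    sim <- tryCatch(
      simulate_barrier_assay(D, q, lambda = 0, n_cells = n_cells,
                             replicates = replicates, record_times = times,
                             seed = cell_seed),
      error = function(e) NULL
    )
    if (is.null(sim)) return(NA_real_)
    sim_vec <- switch(
      data_type,
      leading_edge = extract_le_summary(sim)$value,
      density_profile = extract_dp_summary(sim)$value,
      clustering = extract_cl_summary(sim)$value
    )
    normalised_error(obs_vec, sim_vec)
  })
  out <- tibble::tibble(D = D_grid[grid$Di], q = q_grid[grid$qi],
                        error = err, replicates = replicates)
  structure(out, data_type = data_type, times = times, seed = seed,
            class = c("error_surface", class(out)))
}

observed_summary <- function(observations, data_type, times) {
  switch(
    data_type,
    leading_edge = {
      tab <- observations$radii
      stopifnot(!is.null(tab))
      means <- tab |>
        dplyr::filter(.data$t %in% times) |>
        dplyr::group_by(.data$t) |>
        dplyr::summarise(value = mean(.data$radius), .groups = "drop") |>
        dplyr::arrange(.data$t)
      stopifnot(nrow(means) == length(times))
      means$value
    },
    density_profile = {
      tab <- observations$profiles
      stopifnot(!is.null(tab))
      means <- tab |>
        dplyr::filter(.data$t %in% times) |>
        dplyr::group_by(.data$t, .data$section) |>
        dplyr::summarise(value = mean(.data$density), .groups = "drop") |>
        dplyr::arrange(.data$t, .data$section)
      means$value
    },
    clustering = {
      tab <- observations$clustering
      stopifnot(!is.null(tab))
      means <- tab |>
        dplyr::filter(.data$t %in% times) |>
        dplyr::group_by(.data$t) |>
        dplyr::summarise(value = mean(.data$pct_isolated) / 100,
                         .groups = "drop") |>
        dplyr::arrange(.data$t)
      stopifnot(nrow(means) == length(times))
      means$value
    }
  )
}

#' Estimate the adhesion strength from a clustering error surface
#'
#' Marginalises the surface over the diffusivity axis (mean error across
#' `D` for each `q`) and returns the set of `q` whose marginal error is
#' within `tolerance_factor` of the marginal minimum, together with a
#' diagnostic for how much more the error varies across `q` than across
#' `D` (large values mean the data type pins down `q` but not `D`).
#'
#' @param surface An `error_surface`.
#' @param tolerance_factor Error multiple defining the interval.
#' @return One-row tibble with `q_hat` (marginal arg-min), `q_low`,
#'   `q_high`, and `q_to_D_variation` (variance of the q-marginal divided
#'   by variance of the D-marginal).
#' @export
estimate_q <- function(surface, tolerance_factor = 2) {
  marg_q <- surface |>
    dplyr::group_by(.data$q) |>
    dplyr::summarise(error = mean(.data$error, na.rm = TRUE),
                     .groups = "drop")
  marg_D <- surface |>
    dplyr::group_by(.data$D) |>
    dplyr::summarise(error = mean(.data$error, na.rm = TRUE),
                     .groups = "drop")
  m <- min(marg_q$error)
  if (max(marg_q$error) - m <= .Machine$double.eps * max(1, m)) {
    warning("the error surface is flat in q: q is not identifiable ",
            "from this data type")
    sel <- rep(TRUE, nrow(marg_q))
  } else {
    sel <- marg_q$error <= tolerance_factor * m
  }
  ratio <- if (nrow(marg_D) > 1 && var(marg_D$error) > 0) {
    var(marg_q$error) / var(marg_D$error)
  } else {
    Inf
  }
  tibble::tibble(
    q_hat = marg_q$q[which.min(marg_q$error)],
    q_low = min(marg_q$q[sel]),
    q_high = max(marg_q$q[sel]),
    q_to_D_variation = ratio
  )
}

#' Diffusivity range conditional on a fixed adhesion strength
#'
#' Reads the row of a leading-edge error surface at the given `q` and
#' returns the `[min, max]` span of diffusivities whose error is within
#' `tolerance_factor` of the row minimum.
#'
#' @param surface An `error_surface`.
#' @param q Adhesion strength; snapped to the nearest grid value with a
#'   warning if off-grid.
#' @param tolerance_factor Error multiple defining the interval.
#' @param resolution Error floor below which cells are indistinguishable
#'   from the minimum (the interval threshold is `tolerance_factor` times
#'   `max(row minimum, resolution)`). For leading-edge surfaces a natural
#'   floor is the squared one-pixel relative radius resolution,
#'   `(delta / R)^2`; with replicate variability coming from the model
#'   alone, surface minima can sit far below what the detector can
#'   distinguish.
#' @return One-row tibble with `q`, `D_hat` (row arg-min), `D_low`,
#'   `D_high`.
#' @export
conditional_D_range <- function(surface, q, tolerance_factor = 2,
                                resolution = 0) {
  qs <- sort(unique(surface$q))
  if (!any(abs(qs - q) < 1e-12)) {
    qq <- qs[which.min(abs(qs - q))]
    warning(sprintf("q = %g is not on the surface grid; using q = %g",
                    q, qq))
    q <- qq
  }
  row <- surface[abs(surface$q - q) < 1e-12 & !is.na(surface$error), ]
  stopifnot(nrow(row) >= 1)
  sel <- row$error <= tolerance_factor * max(min(row$error), resolution)
  tibble::tibble(q = q,
                 D_hat = row$D[which.min(row$error)],
                 D_low = min(row$D[sel]),
                 D_high = max(row$D[sel]))
}
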