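#' Normalised least-squares error between observed and simulated summaries
#'
#' All four goodness-of-fit measures share one form: the sum of squared
#' differences between observed and simulated values, divided by the sum of
#' squared observed values. The measure is zero iff the two agree exactly
#' and is invariant to rescaling both by a common factor.
#'
#' @param observed,simulated Numeric vectors (or matrices) of equal shape;
#'   `observed` must not be identically zero.
#' @return A non-negative scalar.
#' @export
normalised_error <- function(observed, simulated) {
  observed <- as.numeric(observed)
  simulated <- as.numeric(simulated)
  if (length(observed) != length(simulated)) {
    stop("observed and simulated summaries must have the same shape")
  }
  denom <- sum(observed^2)
  if (denom == 0) stop("degenerate observation: all observed values are zero")
  sum((observed - simulated)^2) / denom
}

#' @rdname normalised_error
#' @details `error_leading_edge()` compares mean colony radii at the two
#'   post-seeding observation times; `error_density_profile()` compares the
#'   full 98-section profiles at both times; `error_clustering()` compares
#'   mean isolated-cell proportions.
#' @export
error_leading_edge <- function(observed, simulated) {
  stopifnot(length(observed) == 2, length(simulated) == 2)
  normalised_error(observed, simulated)
}

#' @rdname normalised_error
#' @export
error_density_profile <- function(observed, simulated) {
  normalised_error(observed, simulated)
}

#' @rdname normalised_error
#' @export
error_clustering <- function(observed, simulated) {
  stopifnot(length(observed) == 2, length(simulated) == 2)
  normalised_error(observed, simulated)
}

#' Solution of the logistic growth equation
#'
#' Non-dimensional density growing as `dc/dt = lambda c (1 - c)`:
#' `c(t) = c0 exp(lambda t) / (1 + c0 (exp(lambda t) - 1))`.
#'
#' @param c0 Initial density in `[0, 1]`.
#' @param lambda Proliferation rate, per hour.
#' @param t Time, hours. Vectorised.
#' @return Density at time `t`, in `[c0, 1]` for `lambda >= 0`.
#' @export
logistic_solution <- function(c0, lambda, t) {
  if (any(c0 < 0 | c0 > 1)) stop("`c0` must lie in [0, 1]")
  e <- exp(lambda * t)
  c0 * e / (1 + c0 * (e - 1))
}

#' Estimate the proliferation rate from subregion density counts
#'
#' Fits the logistic growth solution to mean non-dimensional densities at
#' the observation times. The initial density `c0` is taken as the observed
#' mean at `t = 0`; the rate `lambda` minimises the normalised
#' least-squares error over the later time points, found on a dense grid
#' (resolution `grid_step`) and refined by golden-section search. The
#' uncertainty range is the set of grid rates whose error is within
#' `range_factor` times the minimum - a declared convention for reading a
#' plausible interval off the one-dimensional error curve.
#'
#' @param densities Tibble with columns `t` (hours) and `density` (and
#'   optionally `replicate`); densities must lie in `[0, 1]`.
#' @param lambda_max Upper end of the search interval, per hour.
#' @param grid_step Grid resolution, per hour.
#' @param range_factor Error multiple defining the uncertainty range.
#' @return A `logistic_fit` object: list with `lambda`, `range` (low,
#'   high), `c0`, `error`, `doubling_time`, and the mean densities used.
#' @export
fit_proliferation_rate <- function(densities, lambda_max = 0.2,
                                   grid_step = 1e-4, range_factor = 2) {
  stopifnot(all(c("t", "density") %in% names(densities)))
  if (any(densities$density < 0 | densities$density > 1)) {
    stop("densities must lie in [0, 1]")
  }
  means <- densities |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(density = mean(.data$density), .groups = "drop") |>
    dplyr::arrange(.data$t)
  if (!any(means$t == 0)) stop("a t = 0 observation is required for c0")
  c0 <- means$density[means$t == 0]
  obs <- means[means$t > 0, ]
  if (nrow(obs) == 0) stop("at least one later observation time is required")
  err_fn <- function(lambda) {
    normalised_error(obs$density, logistic_solution(c0, lambda, obs$t))
  }
  grid <- seq(0, lambda_max, by = grid_step)
  errs <- vapply(grid, err_fn, numeric(1))
  i <- which.min(errs)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  lambda_hat <- if (hi > lo) {
    opt <- optimize(err_fn, c(lo, hi))
    if (opt$objective < errs[i]) opt$minimum else grid[i]
  } else {
    grid[i]
  }
  err_min <- err_fn(lambda_hat)
  in_range <- errs <= max(range_factor * err_min, min(errs))
  structure(
    list(lambda = lambda_hat,
         range = c(low = min(grid[in_range]), high = max(grid[in_range])),
         c0 = c0, error = err_min,
         doubling_time = if (lambda_hat > 0) doubling_time(lambda_hat)
                         else Inf,
         observed = means),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> lambda = %.4f /h (%.4f, %.4f), c0 = %.4f\n",
    x$lambda, x$range[["low"]], x$range[["high"]], x$c0))
  cat(sprintf("  doubling time %.3g h, min normalised error %.3g\n",
              x$doubling_time, x$error))
  invisible(x)
}

#' Fitted logistic densities at given times
#'
#' @param object A `logistic_fit`.
#' @param times Times (hours); defaults to the observed times.
#' @param ... Unused.
#' @return Tibble with `t` and fitted `density`.
#' @export
predict.logistic_fit <- function(object, times = NULL, ...) {
  times <- times %||% object$observed$t
  tibble::tibble(t = times,
                 density = logistic_solution(object$c0, object$lambda,
                                             times))
}
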