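#' Tidy a logistic growth fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `low`, `high` (the error-ratio uncertainty range, for `lambda` only).
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "c0"),
    estimate = c(x$lambda, x$c0),
    low = c(x$range[["low"]], NA_real_),
    high = c(x$range[["high"]], NA_real_)
  )
}

#' @rdname tidy.logistic_fit
#' @return For `glance()`: a one-row tibble with `lambda`, `c0`,
#'   `doubling_time`, and the minimised normalised `error`.
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, c0 = x$c0,
                 doubling_time = x$doubling_time, error = x$error)
}

#' Tidy a colony calibration
#'
#' @param x A `colony_calibration`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`q`, `D`): point estimate
#'   and interval bounds.
#' @export
tidy.colony_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("q", "D"),
    estimate = c(x$q_estimate$q_hat, x$D_estimate$D_hat),
    low = c(x$q_estimate$q_low, x$D_estimate$D_low),
    high = c(x$q_estimate$q_high, x$D_estimate$D_high)
  )
}

#' @rdname tidy.colony_calibration
#' @return For `glance()`: a one-row tibble with the point estimates, the
#'   q-to-D variation diagnostic, and the tolerance factor used.
#' @export
glance.colony_calibration <- function(x, ...) {
  tibble::tibble(
    q_hat = x$q_estimate$q_hat,
    D_hat = x$D_estimate$D_hat,
    q_to_D_variation = x$q_estimate$q_to_D_variation,
    tolerance_factor = x$tolerance_factor
  )
}
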