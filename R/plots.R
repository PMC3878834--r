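#' Plot an error surface over the (D, q) grid
#'
#' @param object An `error_surface`.
#' @param ... Unused.
#' @return A ggplot: tiles coloured by log10 error.
#' @export
autoplot.error_surface <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$D, y = .data$q,
                               fill = log10(.data$error))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 error") +
    ggplot2::labs(
      x = expression(D ~ (mu * m^2 ~ h^-1)),
      y = "adhesion strength q",
      title = paste("Normalised least-squares error:",
                    attr(object, "data_type"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a logistic growth fit against the observed densities
#'
#' @param object A `logistic_fit`.
#' @param ... Unused.
#' @return A ggplot of the fitted curve with observed means overlaid.
#' @export
autoplot.logistic_fit <- function(object, ...) {
  tmax <- max(object$observed$t)
  curve <- predict(object, times = seq(0, tmax, length.out = 200))
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t, y = .data$density)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(data = object$observed, size = 2) +
    ggplot2::labs(x = "time (h)", y = "non-dimensional density c(t)",
                  title = sprintf("lambda = %.4f per h (doubling %.3g h)",
                                  object$lambda, object$doubling_time)) +
    ggplot2::theme_minimal()
}

#' Plot a radius time series
#'
#' @param radii Tibble with `replicate`, `t`, `radius` (micrometres), e.g.
#'   the `radii` table of an observation set.
#' @return A ggplot of mean radius (mm) with one-standard-deviation bars.
#' @export
plot_radius_series <- function(radii) {
  summ <- radii |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(mean = mean(.data$radius) / 1000,
                     sd = sd(.data$radius) / 1000, .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$t, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "time (h)", y = "equivalent radius (mm)") +
    ggplot2::theme_minimal()
}

#' Plot density profiles along the transect
#'
#' @param profiles Tibble with `t`, `r_um`, `density` (optionally
#'   `replicate`, averaged away).
#' @return A ggplot of the mean profile per time point.
#' @export
plot_density_profile <- function(profiles) {
  summ <- profiles |>
    dplyr::group_by(.data$t, .data$r_um) |>
    dplyr::summarise(density = mean(.data$density), .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(x = .data$r_um / 1000, y = .data$density,
                               colour = factor(.data$t))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position along transect (mm)",
                  y = "non-dimensional density c(r, t)",
                  colour = "t (h)") +
    ggplot2::theme_minimal()
}
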