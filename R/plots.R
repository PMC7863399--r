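#' Plot an occurrence distribution
#'
#' Raster of occurrence heights with the availability contour cells outlined.
#'
#' @param object An `occurrence_dist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.occurrence_dist <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$height)) +
    ggplot2::geom_tile(
      data = dplyr::filter(d, .data$in_mask),
      fill = NA, colour = "grey80", linewidth = 0.05
    ) +
    ggplot2::scale_fill_viridis_c(name = "height") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = if (length(object$meta)) {
        paste(unlist(object$meta), collapse = " / ")
      } else "Occurrence distribution",
      x = "x (m)", y = "y (m)"
    )
}

#' Plot two circular activity densities and their overlap
#'
#' @param object An `overlap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_result <- function(object, ...) {
  d <- tidy(object)
  dmin <- tibble::tibble(
    time = object$density_a$time,
    density = pmin(object$density_a$density, object$density_b$density)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$density)) +
    ggplot2::geom_area(
      data = dmin, fill = "grey80",
      ggplot2::aes(x = .data$time, y = .data$density)
    ) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$group)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::labs(
      x = "time of day (h)", y = "activity density",
      colour = NULL,
      title = sprintf("Coefficient of overlapping = %.2f", object$delta)
    )
}

#' Forest plot of population RUF coefficients
#'
#' Standardized population-mean coefficients with their confidence intervals.
#'
#' @param object A `population_ruf`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.population_ruf <- function(object, ...) {
  d <- dplyr::filter(tidy(object), .data$term != "intercept")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)
    ) +
    ggplot2::labs(
      x = "standardized coefficient", y = NULL,
      title = if (length(object$meta)) {
        paste(unlist(object$meta), collapse = " / ")
      } else "Population RUF"
    )
}

#' Plot a dynamic motion-variance profile
#'
#' @param object A `motion_variance_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motion_variance_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$segment, y = .data$sigma_m2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "segment", y = expression(sigma[m]^2 ~ (m^2 / min)))
}
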