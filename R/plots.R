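# ggplot2 views of the main result types.

#' @export
autoplot.fill_result <- function(object, ...) {
  d <- dplyr::filter(object$data, !is.na(.data$observed))
  ggplot2::ggplot(d, ggplot2::aes(.data$observed, .data$prediction)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE,
      colour = "black", linewidth = 0.4
    ) +
    ggplot2::labs(
      title = paste("Gap filling:", toupper(object$method)),
      x = expression(observed ~ F[C] ~ (mu * mol ~ m^-2 ~ s^-1)),
      y = expression(predicted ~ F[C] ~ (mu * mol ~ m^-2 ~ s^-1))
    )
}

#' Fingerprint (day x hour) heatmap of a filled series
#'
#' @param result A `fill_result`.
#' @return A ggplot.
#' @export
plot_fingerprint <- function(result) {
  d <- dplyr::mutate(
    result$data,
    date = as.Date(format(.data$timestamp, "%Y-%m-%d")),
    hour = decimal_hour(.data$timestamp)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$date, .data$hour, fill = .data$filled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "darkgreen", mid = "white", high = "brown", midpoint = 0,
      name = expression(F[C])
    ) +
    ggplot2::labs(
      title = paste("Fingerprint:", toupper(result$method)),
      x = NULL, y = "hour of day"
    )
}

#' Cumulative carbon-exchange curves for several methods
#'
#' @param results A list of `fill_result` objects.
#' @return A ggplot; each curve ends at that method's annual sum.
#' @export
plot_cumulative <- function(results) {
  d <- purrr::map_dfr(results, function(r) {
    dplyr::mutate(
      cumulative_exchange(r$data$filled, r$data$timestamp),
      method = toupper(r$method)
    )
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$timestamp, .data$cum_gC,
    colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = NULL, y = expression(cumulative ~ CO[2] ~ exchange ~ (g ~ C ~ m^-2)),
      colour = NULL
    )
}

#' @export
autoplot.sigma_model <- function(object, ...) {
  ggplot2::ggplot(object$bin_table, ggplot2::aes(.data$center, .data$sd_resid)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      slope = object$b, intercept = object$a,
      colour = "red"
    ) +
    ggplot2::labs(
      x = expression("|" * F[C] * "|" ~ (mu * mol ~ m^-2 ~ s^-1)),
      y = expression(sigma(epsilon) ~ (mu * mol ~ m^-2 ~ s^-1)),
      title = sprintf(
        "sd(eps) = %.2f + %.3f |F_C| (r2 = %.2f)",
        object$a, object$b, object$r_squared
      )
    )
}

#' @export
autoplot.laplace_fit <- function(object, ...) {
  d <- tibble::tibble(residual = object$sample)
  xs <- seq(min(d$residual), max(d$residual), length.out = 400)
  dens <- tibble::tibble(
    x = xs,
    y = exp(-abs(xs - object$location) / object$scale) / (2 * object$scale)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$residual)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      bins = 60, fill = "grey80", colour = "grey40"
    ) +
    ggplot2::geom_line(
      data = dens, ggplot2::aes(.data$x, .data$y),
      colour = "red"
    ) +
    ggplot2::labs(
      x = expression(residual ~ (mu * mol ~ m^-2 ~ s^-1)), y = "density",
      title = sprintf(
        "Laplace fit: location %.2f, scale %.2f, excess kurtosis %.1f",
        object$location, object$scale, object$excess_kurtosis
      )
    )
}

#' @export
autoplot.ustar_result <- function(object, ...) {
  ggplot2::ggplot(
    object$level_table,
    ggplot2::aes(.data$mean_ustar, .data$mean_flux)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$threshold, colour = "red",
      linetype = 2
    ) +
    ggplot2::labs(
      x = expression(u["*"] ~ (m ~ s^-1)),
      y = expression(mean ~ nighttime ~ F[C] ~ (mu * mol ~ m^-2 ~ s^-1)),
      title = sprintf("u* threshold scan: %.3f m s-1", object$threshold)
    )
}

#' @export
autoplot.gap_stats <- function(object, ...) {
  d <- tibble::tibble(hours = object$run_lengths / 2)
  ggplot2::ggplot(d, ggplot2::aes(.data$hours)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "gap length (h)", y = "count")
}
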