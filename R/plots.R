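# ggplot2 figures for the result types.

#' Plot a condition table in growth-law coordinates
#'
#' Ribosomal mass fraction against growth rate, optionally with the fitted
#' first-growth-law line overlaid.
#'
#' @param conditions Condition table with `growth_rate_per_h` and
#'   `ribosome_fraction`.
#' @param fit Optional `growth_law_fit` to overlay.
#' @return A ggplot object.
#' @export
plot_growth_law <- function(conditions, fit = NULL) {
  p <- ggplot2::ggplot(conditions,
                       ggplot2::aes(x = .data$growth_rate_per_h,
                                    y = .data$ribosome_fraction)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda ~ "(1/h)"),
                  y = expression(phi[R])) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(intercept = fit$intercept,
                                  slope = fit$slope, colour = "steelblue")
  }
  p
}

#' Plot the ribosome partition across growth rates
#'
#' Stacked view of the bound fraction and its growth/maintenance split
#' against growth rate, from a [partition_ribosomes()] table.
#'
#' @param partitions Output of [partition_ribosomes()].
#' @return A ggplot object.
#' @export
plot_partition <- function(partitions) {
  long <- tidyr::pivot_longer(
    partitions[, c("growth_rate_per_h", "f_a", "f_b", "f_bm")],
    cols = c("f_a", "f_b", "f_bm"),
    names_to = "fraction", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$growth_rate_per_h,
                                     y = .data$value,
                                     colour = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(lambda ~ "(1/h)"), y = "fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname saturated_linear_fit
#' @method autoplot saturated_fit
#' @export
autoplot.saturated_fit <- function(object, ...) {
  grid <- seq(min(object$x), max(object$x), length.out = 200)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = tibble::tibble(x = object$x, y = object$y),
                        ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(
      data = tibble::tibble(x = grid, y = predict(object, grid)),
      ggplot2::aes(x = .data$x, y = .data$y), colour = "forestgreen"
    ) +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = "dashed") +
    ggplot2::labs(x = object$xname, y = object$yname) +
    ggplot2::theme_minimal()
}

#' @rdname fit_three_class
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  df <- tibble::tibble(time_h = object$curve$time_h,
                       observed = object$curve$labelled_fraction,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "chase time (h)", y = "labelled fraction") +
    ggplot2::theme_minimal()
}
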