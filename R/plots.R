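# ggplot2 display methods for the result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.dr_fit <- function(object, n_grid = 200, ...) {
  label <- if (object$mode == "ic50") "IC50" else "appKD"
  rng <- range(object$data$dose)
  grid <- tibble::tibble(
    dose = 10^seq(log10(rng[1]), log10(rng[2]), length.out = n_grid)
  )
  cf <- setNames(object$coefficients$estimate, object$coefficients$term)
  grid$response <- fourpl(grid$dose, cf[["bottom"]], cf[["top"]], cf[["mid"]],
                          cf[["hill"]], object$direction)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$mid, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("dose (%s)", ifelse(is.na(object$unit), "a.u.", object$unit)),
      y = "response",
      title = sprintf("4PL fit: %s = %.3g %s", label, object$mid,
                      ifelse(is.na(object$unit), "", object$unit))
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.melt_result <- function(object, ...) {
  t_half <- tryCatch(compute_t_half(object), error = function(e) NA_real_)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$temperature_C,
                                    y = .data$emission_norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted") +
    ggplot2::labs(x = "temperature (°C)", y = "normalized FAM emission (%)",
                  title = if (is.na(t_half)) "melting curve" else
                    sprintf("melting curve, T1/2 = %.2f °C", t_half)) +
    ggplot2::theme_minimal()
  if (!is.na(t_half)) {
    p <- p + ggplot2::geom_vline(xintercept = t_half, linetype = "dashed")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.synergy_matrix <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = factor(.data$dose_b),
                               y = factor(.data$dose_a),
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  name = "Bliss score") +
    ggplot2::labs(x = "drug B dose", y = "drug A dose",
                  title = sprintf("Bliss excess (mean %.1f)", object$mean_score)) +
    ggplot2::theme_minimal()
}

#' Condition-summary plot
#'
#' Bars of across-experiment mean foci per cell with SD error bars, one
#' metric at a time, ordered with the untreated condition first.
#'
#' @param summaries Output of [summarize_condition()] (possibly several
#'   metrics bound together).
#' @param metric Which metric to show.
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(summaries, metric = "nuclear") {
  df <- dplyr::filter(summaries, .data$metric == !!metric)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$condition,
                                                      .data$delta),
                                   y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = sprintf("%s foci per cell", metric)) +
    ggplot2::theme_minimal()
}
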