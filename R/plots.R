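# ggplot2 visualisations of the result objects

#' @export
autoplot.mixtox_drc <- function(object, n_grid = 200, ...) {
  stopifnot(!is.null(object$data))
  conc <- object$data$concentration
  pos <- conc[conc > 0]
  grid <- c(0, exp(seq(log(min(pos)) - 1, log(max(pos)) + 0.5,
                       length.out = n_grid)))
  curve <- tibble::tibble(concentration = grid,
                          response = predict(object, grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::scale_x_continuous(trans = "log1p", name = "concentration") +
    ggplot2::labs(y = "response",
                  title = sprintf("Log-logistic fit%s (EC50 = %.3g)",
                                  if (!is.na(object$chemical))
                                    paste0(": ", object$chemical) else "",
                                  object$ec50)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mixtox_surface <- function(object, ...) {
  d <- object$data
  d$fitted <- predict_surface(object$params, object$model_type, d$c1, d$c2)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$response)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "fitted response", y = "observed response",
                  title = sprintf("%s surface (%s deviation), R2 = %.2f",
                                  object$model_type,
                                  object$params$deviation_kind, object$R2)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mixtox_elimination <- function(object, n_grid = 100, ...) {
  d <- object$data
  grid <- tibble::tibble(
    time = seq(0, max(d$time), length.out = n_grid))
  grid$concentration <- object$C0 * exp(-object$k * grid$time)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$concentration)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "time since transfer to clean water (d)",
                  y = "tissue concentration",
                  title = sprintf("First-order elimination: k = %.3g / d%s",
                                  object$k,
                                  if (!object$no_elimination)
                                    sprintf(" (t1/2 = %.3g d)",
                                            object$half_life) else "")) +
    ggplot2::theme_minimal()
}

#' Bar chart of enriched GO terms
#'
#' @param results An [enrich()] result tibble.
#' @param max_terms Show at most this many terms (by p-value).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, max_terms = 20) {
  d <- head(results[results$enriched, , drop = FALSE], max_terms)
  if (nrow(d) == 0) {
    stop_mixtox("No enriched terms to plot.", "mixtoxsys_usage_error")
  }
  d$label <- ifelse(is.na(d$name), d$term, paste0(d$name, " (", d$term, ")"))
  ggplot2::ggplot(d, ggplot2::aes(x = 100 * .data$k / .data$n,
                                  y = stats::reorder(.data$label, -.data$p))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "relative frequency in study list (%)", y = NULL,
                  title = "Over-represented GO terms") +
    ggplot2::theme_minimal()
}
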