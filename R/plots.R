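#' Plot a choice distribution
#'
#' @param object An [choice_distribution()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.srdt_choice <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$lottery_id, y = .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "choice probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an experiment curve table
#'
#' Dispatches on the curve's columns: fourfold tables are drawn as choice
#' probability versus outcome probability by task; time-pressure tables as
#' choice probability versus the (log) time budget.
#'
#' @param object An `srdt_curve` tibble from [fourfold_curves()] or
#'   [time_pressure_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.srdt_curve <- function(object, ...) {
  if ("prob_risky" %in% names(object)) {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$p,
                                              y = .data$prob_risky,
                                              colour = .data$task)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "outcome probability p",
                    y = "P(choose risky lottery)")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$T,
                                              y = .data$prob_low_risk)) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "time budget T", y = "P(choose low-risk lottery)")
  }
  p +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::theme_minimal()
}

#' Plot a derived probability-weighting curve
#'
#' @param shape A [weighting_shape()] result.
#' @return A ggplot of \eqn{\pi(p|T)} against the identity line.
#' @export
plot_weighting <- function(shape) {
  ggplot2::ggplot(shape$curve, ggplot2::aes(x = .data$p, y = .data$pi)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "objective probability p",
                  y = expression(pi(p)),
                  title = paste("shape:", shape$shape)) +
    ggplot2::theme_minimal()
}
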