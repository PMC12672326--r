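#' Plot cost-effectiveness acceptability curves
#'
#' @param x A `cua_ceac` object.
#' @param thresholds Optional WTP values to mark with vertical lines.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, thresholds = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  g <- ggplot2::ggplot(x$curve,
                       ggplot2::aes(x = .data$wtp, y = .data$probability,
                                    colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness-to-pay (USD/QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds))
    g <- g + ggplot2::geom_vline(xintercept = thresholds, linetype = "dotted")
  g
}

#' Plot a tornado diagram
#'
#' Horizontal bars from the ICUR at each parameter's lower bound to the
#' ICUR at its upper bound, ranked by spread, with the base-case ICUR as a
#' reference line.
#'
#' @param x A `cua_tornado` from [one_way_sa()].
#' @param top Show only the `top` widest parameters (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(x, top = nrow(x)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab <- x[!x$dominance_flag, , drop = FALSE]
  tab <- utils::head(tab[order(-tab$spread), , drop = FALSE], top)
  tab$parameter <- factor(tab$parameter, levels = rev(tab$parameter))
  ggplot2::ggplot(tab,
                  ggplot2::aes(y = .data$parameter,
                               xmin = pmin(.data$icur_at_low, .data$icur_at_high),
                               xmax = pmax(.data$icur_at_low, .data$icur_at_high))) +
    ggplot2::geom_linerange(linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(x, "base_icur"), linetype = "dashed") +
    ggplot2::labs(x = "ICUR (USD/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}
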