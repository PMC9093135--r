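# Convenience figures; never load-bearing for the analysis.

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param tornado output of [one_way_dsa()] / [run_dsa()].
#' @param base_icer optional base-case ICER drawn as a vertical line.
#' @return a ggplot object.
#' @export
plot_tornado <- function(tornado, base_icer = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- tornado[tornado$flag == "" & tornado$width > 0, ]
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  gg <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = pmin(.data$icer_low, .data$icer_high),
      xend = pmax(.data$icer_low, .data$icer_high),
      y = .data$parameter, yend = .data$parameter), linewidth = 5) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(base_icer)) {
    gg <- gg + ggplot2::geom_vline(xintercept = base_icer, linetype = 2)
  }
  gg
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_df output of [ceac()].
#' @param wtp optional threshold drawn as a vertical line.
#' @return a ggplot object.
#' @export
plot_ceac <- function(ceac_df, wtp = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  gg <- ggplot2::ggplot(ceac_df,
                        ggplot2::aes(x = .data$wtp, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) gg <- gg + ggplot2::geom_vline(xintercept = wtp, linetype = 2)
  gg
}
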