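#' Plot the incremental cost-effectiveness plane
#'
#' Scatter of per-iteration incremental (QALY, cost) pairs with the
#' willingness-to-pay line. Points in the south-east quadrant show the
#' intervention both cheaper and more effective.
#'
#' @param psa A `cea_psa` from [run_psa()].
#' @param threshold Willingness-to-pay line to draw, EUR per QALY.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, threshold = psa$wtp_threshold) {
  if (!inherits(psa, "cea_psa")) abort_validation("`psa` must be a cea_psa")
  it <- psa$iterations
  ggplot2::ggplot(it, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                                   colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = threshold, intercept = 0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "Incremental QALYs (TOLAC - ERCD)",
      y = "Incremental cost, EUR (TOLAC - ERCD)",
      colour = "Quadrant",
      title = "Cost-effectiveness plane",
      subtitle = sprintf("%d Monte Carlo iterations; dashed line EUR %s/QALY",
                         psa$n_iter, format(threshold, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param curve A data.frame from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  if (!is.data.frame(curve) || !all(c("threshold", "probability") %in% names(curve))) {
    abort_validation("`curve` must be a data.frame from ceac()")
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay, EUR per QALY",
                  y = "P(TOLAC cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
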