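#' Force trace plot
#'
#' Recorded external-spring force with a sliding-window average and the
#' time-mean overlaid, mirroring the usual presentation of contraction
#' traces.
#'
#' @param object A [simulate_sarcomere()] result.
#' @param window Smoothing window, s.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sarcomere_trace <- function(object, window = 0.012, ...) {
  d <- object$samples
  d$smoothed <- sliding_window(d$force, window, d$time)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$force),
                        size = 0.3, alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed), colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = mean(d$force), linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "force (pN)",
                  title = sprintf("%d-myosin half-sarcomere force",
                                  object$lattice$n_myosin)) +
    ggplot2::theme_minimal()
}

#' Concentration-grid heatmap
#'
#' Phase-diagram view of a steady-state or sweep table over `[ATP]` and
#' `[ADP][Pi]`, on log axes with a log-scaled fill.
#'
#' @param grid A [concentration_grid()] table or the `points` table of a
#'   [run_sweep()].
#' @param fill Column to colour by (tidy-eval), default `duty_ratio`.
#' @return A ggplot object.
#' @export
plot_concentration_grid <- function(grid, fill = duty_ratio) {
  fill <- rlang::enquo(fill)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$atp, y = .data$adppi,
                                     fill = !!fill)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "[ATP] (M)", y = "[ADP][Pi] (M^2)") +
    ggplot2::theme_minimal()
}
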