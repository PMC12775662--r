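#' Heatmap of a retention-probability grid
#'
#' Plots P_r over the (theta, nu) plane: dark red for retention, cream for
#' loss, with a vertical line marking the maximum unused-retention time for
#' the grid's (tau, eta_max).
#'
#' @param grid A [sweep_grid()] result.
#' @param mark_delta_t_max Draw the vertical maximum-time line.
#' @return A ggplot object.
#' @export
plot_retention_grid <- function(grid, mark_delta_t_max = TRUE) {
  stopifnot(inherits(grid, "retention_grid"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
  df <- as.data.frame(grid)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$nu,
                                        fill = .data$p_r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#fdf5e6", high = "#8b0000",
                                 limits = c(0, 1),
                                 name = "P(retention)") +
    ggplot2::labs(
      x = "mean use interval θ (years)",
      y = "variability ν",
      title = sprintf("Skill retention over %g years (τ = %g yr, ηmax = %g)",
                      grid$spec$L, grid$spec$tau, grid$spec$eta_max)) +
    ggplot2::coord_cartesian(expand = FALSE)
  if (mark_delta_t_max && grid$delta_t_max <= max(grid$spec$theta_values)) {
    p <- p + ggplot2::geom_vline(xintercept = grid$delta_t_max,
                                 colour = "steelblue", linewidth = 0.8)
  }
  p
}
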