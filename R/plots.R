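#' Render the standard figures for an experiment result
#'
#' Produces the four standard views of a run: a position-ordered raster of
#' input and network spikes, confidence maps over the four tuning
#' dimensions, decoded-trajectory traces against the true dot path with
#' per-phase MSE annotated, and a connectivity fan plot for a single neuron
#' with delays color-coded and the anisotropy statistic annotated.
#'
#' @param res An `experiment_result` from [run_experiment()].
#' @param out_dir Optional directory; when given, each figure is saved as
#'   PNG.
#' @param fan_neuron Excitatory neuron whose connections are fanned out.
#' @return Named list of ggplot objects (`raster`, `confidence`, `readout`,
#'   `fan`), invisibly when saving.
#' @export
render_outputs <- function(res, out_dir = NULL, fan_neuron = 1L) {
  figs <- list(raster = plot_raster(res),
               confidence = plot_confidence_maps(res),
               readout = plot_readout(res),
               fan = plot_connectivity_fan(res$synapses$EE, res$tuning$E,
                                           fan_neuron))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(figs)) {
      ggplot2::ggsave(file.path(out_dir, paste0(nm, ".png")), figs[[nm]],
                      width = 8, height = 6, dpi = 150)
    }
    return(invisible(figs))
  }
  figs
}

#' Position-ordered spike raster
#'
#' Excitatory neurons are ordered by the x coordinate of their receptive
#' field; input spikes are drawn behind network spikes. Phase boundaries are
#' dashed.
#'
#' @param res An `experiment_result`.
#' @return A ggplot object.
#' @export
plot_raster <- function(res) {
  ord <- order(res$tuning$E$x)
  rank_of <- integer(nrow(res$tuning$E)); rank_of[ord] <- seq_along(ord)
  spikes_e <- res$spikes[res$spikes$population == "E", , drop = FALSE]
  df <- rbind(
    if (nrow(res$input_spikes))
      data.frame(time = res$input_spikes$time,
                 pos = rank_of[res$input_spikes$neuron_id], what = "input"),
    if (nrow(spikes_e))
      data.frame(time = spikes_e$time, pos = rank_of[spikes_e$neuron_id],
                 what = "network"))
  p <- ggplot2::ggplot() +
    ggplot2::labs(x = "time (ms)", y = "neuron (ordered by x position)") +
    ggplot2::theme_minimal()
  if (!is.null(df) && nrow(df)) {
    p <- p + ggplot2::geom_point(
      data = df,
      ggplot2::aes(x = .data$time, y = .data$pos, color = .data$what),
      size = 0.2, alpha = 0.4) +
      ggplot2::scale_color_manual(values = c(input = "steelblue",
                                             network = "black"))
  }
  p + ggplot2::geom_vline(xintercept = res$config$protocol$phases$t_start,
                          linetype = "dashed", linewidth = 0.3)
}

#' Four-panel confidence maps
#'
#' Accumulated per-bin confidence over the tuning dimensions x, y, u, v,
#' color-coded through time.
#'
#' @param res An `experiment_result`.
#' @param n_bins Tuning-dimension bins.
#' @return A ggplot object (faceted).
#' @export
plot_confidence_maps <- function(res, n_bins = 20) {
  conf <- attr(res$decoded, "confidence")
  dfs <- lapply(c("x", "y", "u", "v"), function(dm) {
    m <- confidence_map(conf$p, res$tuning$E, dm, n_bins)
    breaks <- attr(m, "breaks")
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    data.frame(time = rep(res$decoded$bin_mid, times = n_bins),
               value = rep(mids, each = nrow(m)),
               confidence = as.vector(m), dimension = dm)
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   fill = .data$confidence)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~dimension, scales = "free_y") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (ms)", y = "tuning value") +
    ggplot2::theme_minimal()
}

#' Decoded trajectory against the true dot path
#'
#' @param res An `experiment_result`.
#' @return A ggplot object.
#' @export
plot_readout <- function(res) {
  truth <- stimulus_position(res$config$protocol, res$decoded$bin_mid)
  df <- rbind(
    data.frame(time = res$decoded$bin_mid, value = res$decoded$x_pred,
               series = "x decoded"),
    data.frame(time = res$decoded$bin_mid, value = truth$x,
               series = "x true"),
    data.frame(time = res$decoded$bin_mid, value = res$decoded$y_pred,
               series = "y decoded"),
    data.frame(time = res$decoded$bin_mid, value = truth$y,
               series = "y true"))
  iv <- res$errors$intervals
  lab <- paste(sprintf("%s %d-%d ms: MSE %.4f", iv$kind, iv$t_start,
                       iv$t_end, iv$mse), collapse = "\n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   color = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = res$config$protocol$phases$t_start,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::annotate("label", x = 0, y = 1.05, label = lab, hjust = 0,
                      vjust = 1, size = 2.5) +
    ggplot2::labs(x = "time (ms)", y = "position (torus units)") +
    ggplot2::theme_minimal()
}

#' Connectivity fan plot for one neuron
#'
#' Outgoing connections of a single neuron drawn as segments from its
#' receptive field to its targets' (minimal-image), color-coded by delay,
#' with the neuron's preferred direction as an arrow and the table's
#' anisotropy statistic annotated.
#'
#' @param ee The E-to-E `synapse_table`.
#' @param tuning Excitatory `tuning_table`.
#' @param neuron Neuron index.
#' @return A ggplot object.
#' @export
plot_connectivity_fan <- function(ee, tuning, neuron = 1L) {
  out <- ee[ee$source_id == neuron, , drop = FALSE]
  x0 <- tuning$x[neuron]; y0 <- tuning$y[neuron]
  disp <- torus_displacement(x0, y0, tuning$x[out$target_id],
                             tuning$y[out$target_id])
  speed <- sqrt(tuning$u[neuron]^2 + tuning$v[neuron]^2)
  aniso <- anisotropy_statistic(ee, tuning)
  df <- data.frame(xend = x0 + disp$dx, yend = y0 + disp$dy,
                   delay = out$delay, weight = out$weight)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = x0, y = y0, xend = .data$xend,
                                       yend = .data$yend,
                                       color = .data$delay,
                                       linewidth = .data$weight),
                          alpha = 0.7) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2)) +
    ggplot2::scale_color_viridis_c(name = "delay (ms)") +
    ggplot2::annotate("segment", x = x0, y = y0,
                      xend = x0 + 0.08 * tuning$u[neuron] / speed,
                      yend = y0 + 0.08 * tuning$v[neuron] / speed,
                      arrow = grid::arrow(length = grid::unit(0.1, "in")),
                      color = "orange", linewidth = 1) +
    ggplot2::annotate("label", x = x0, y = y0 - 0.45,
                      label = sprintf("anisotropy statistic: %.4f", aniso),
                      size = 3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}
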