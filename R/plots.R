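#' Scree plot of an embedding basis
#'
#' @param object A `dd_embedding`.
#' @param ... Unused.
#' @export
autoplot.dd_embedding <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$energy_fraction,
                                   fill = .data$kept)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "singular mode", y = "energy fraction",
                  fill = "kept") +
    ggplot2::theme_minimal()
}

#' Per-label discriminability of a decode result
#'
#' @param object A `dd_decode_result`.
#' @param ... Unused.
#' @export
autoplot.dd_decode_result <- function(object, ...) {
  ggplot2::ggplot(object$per_label,
                  ggplot2::aes(x = .data$label, y = .data$f1)) +
    ggplot2::geom_col(fill = "darkred") +
    ggplot2::geom_hline(yintercept = object$ccr, linetype = 2) +
    ggplot2::labs(x = "stimulus", y = "F1 score",
                  title = sprintf("%s decoding (CCR = %.3f)",
                                  object$mode, object$ccr)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot embedded trajectories in a 2-D projection
#'
#' @param trajectories Trajectory tibble from [expand_and_center()].
#' @param dims Two dimensions to plot (default 1:2).
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajectories, dims = c(1, 2)) {
  df <- dplyr::bind_rows(lapply(seq_len(nrow(trajectories)), function(i) {
    p <- trajectories$points[[i]]
    tibble::tibble(trial_id = trajectories$trial_id[i],
                   stimulus = factor(trajectories$stimulus_index[i]),
                   x = p[, dims[1]], y = p[, dims[2]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$trial_id,
                                   colour = .data$stimulus)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.3) +
    ggplot2::labs(x = sprintf("PC%d", dims[1]), y = sprintf("PC%d", dims[2])) +
    ggplot2::theme_minimal()
}

#' Tuning curve with reliability
#'
#' @param summary Output of [tuning_summary()].
#' @return A ggplot of mean deflection (with sd error bars) per stimulus.
#' @export
plot_tuning <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$stimulus_index,
                                        y = .data$mean_deflection)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_deflection - .data$sd_deflection,
      ymax = .data$mean_deflection + .data$sd_deflection),
      colour = "purple") +
    ggplot2::geom_line(colour = "purple") +
    ggplot2::labs(x = "stimulus ordinal", y = "mean |deflection|") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
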