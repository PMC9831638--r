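# ggplot2 views of the main result objects.

#' Plot a patch as a raster image
#'
#' @param patch Pixel vector or `W x W` matrix.
#' @param title Optional title.
#' @export
plot_patch <- function(patch, title = NULL) {
  v <- as_patch_vector(patch)
  W <- as.integer(round(sqrt(length(v))))
  df <- tidyr::expand_grid(row = seq_len(W), col = seq_len(W))
  df$value <- v
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "grey50",
                                  high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_closed_loop Autoplot of activity, belief and feedback
#'   cost over time.
#' @param object An `ac_trace`.
#' @param ... Unused.
#' @export
autoplot.ac_trace <- function(object, ...) {
  st <- object$steps
  long <- if (object$task == "localization") {
    tidyr::pivot_longer(
      st[, c("t", "activity", "feedback_cost", "sq_error")],
      -"t", names_to = "series")
  } else {
    tidyr::pivot_longer(
      st[, c("t", "activity", "feedback_cost", "posterior")],
      -"t", names_to = "series")
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time step", y = NULL,
                  title = sprintf("%s task, %s code", object$task,
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' @describeIn build_threshold_table Autoplot: mean threshold per grid
#'   point.
#' @param object An `ac_threshold_table`.
#' @param ... Unused.
#' @export
autoplot.ac_threshold_table <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$point, .data$grid) |>
    dplyr::summarise(mean_xi = mean(.data$xi), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$point, .data$mean_xi)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "belief grid point", y = "mean threshold",
                  title = sprintf("%s thresholds (psi = %g)", object$task,
                                  object$psi)) +
    ggplot2::theme_minimal()
}

#' Plot an ROI compression sweep
#'
#' Activity suppression and ROI reconstruction quality against the
#' attentional resource constraint.
#'
#' @param sweep Tibble from [roi_compress()].
#' @export
plot_roi_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep[, c("psi", "activity", "snr_roi")],
                              -"psi", names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(.data$psi, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "attentional resource constraint",
                  y = NULL) +
    ggplot2::theme_minimal()
}
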