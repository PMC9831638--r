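# broom-style tidiers for the package's result objects.

#' Tidy a simulation trace
#'
#' @param x An `ac_trace`.
#' @param ... Unused.
#' @return The per-step tibble of the trace.
#' @export
tidy.ac_trace <- function(x, ...) x$steps

#' One-row summary of a simulation trace
#'
#' @param x An `ac_trace`.
#' @param ... Unused.
#' @export
glance.ac_trace <- function(x, ...) {
  st <- x$steps
  out <- tibble::tibble(
    task = x$task, mode = x$mode, T = nrow(st),
    mean_activity = mean(st$activity),
    mean_feedback_cost = mean(st$feedback_cost),
    switch_rate = mean(st$xi_changed))
  if (x$task == "localization") {
    out$mean_sq_error <- mean(st$sq_error)
  } else {
    out$mean_posterior_true <- mean(ifelse(st$state == 1L, st$posterior,
                                           1 - st$posterior))
  }
  out
}

#' Tidy a threshold table
#'
#' @param x An `ac_threshold_table`.
#' @param ... Unused.
#' @return Long tibble: grid point, neuron, threshold.
#' @export
tidy.ac_threshold_table <- function(x, ...) {
  K <- nrow(x$xi)
  grid_lab <- if (is.matrix(x$grid)) {
    sprintf("(%g, %g)", x$grid[, 1], x$grid[, 2])
  } else as.character(signif(x$grid, 4))
  tidyr::expand_grid(point = seq_len(K), neuron = seq_len(ncol(x$xi))) |>
    dplyr::mutate(grid = grid_lab[.data$point],
                  xi = as.numeric(t(x$xi))[
                    (.data$point - 1) * ncol(x$xi) + .data$neuron],
                  valid = x$valid[.data$point])
}

#' One-row summary of a threshold table
#'
#' @param x An `ac_threshold_table`.
#' @param ... Unused.
#' @export
glance.ac_threshold_table <- function(x, ...) {
  tibble::tibble(task = x$task, psi = x$psi, points = nrow(x$xi),
                 neurons = ncol(x$xi), valid = sum(x$valid),
                 mean_xi = mean(x$xi[x$valid, ]))
}

#' Tidy a threshold optimization result
#'
#' @param x An `ac_xi_opt`.
#' @param ... Unused.
#' @return Tibble of the accepted-cost trace.
#' @export
tidy.ac_xi_opt <- function(x, ...) {
  tibble::tibble(step = seq_along(x$trace) - 1, cost = x$trace)
}

#' Tidy a dictionary
#'
#' @param x An `ac_dictionary`.
#' @param ... Unused.
#' @return Per-neuron tibble: centroid and dominant orientation.
#' @export
tidy.ac_dictionary <- function(x, ...) {
  ctr <- atom_centroids(x)
  tibble::tibble(neuron = seq_len(x$N), centroid_row = ctr[, 1],
                 centroid_col = ctr[, 2],
                 orientation = atom_orientations(x))
}
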