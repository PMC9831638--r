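#' Generate a binary latent-state sequence
#'
#' Either a telegraph process (state flips each step with probability `h`)
#' or the deterministic scripted environment of blocks of
#' positive / negative / positive states (default 50/100/50 per cycle),
#' repeated `n_cycles` times and truncated to `T` when given.
#'
#' @param T Length (required for telegraph mode; optional truncation for
#'   scripted mode).
#' @param h Hazard rate.
#' @param mode `"telegraph"` or `"scripted"`.
#' @param cycle Scripted block lengths (positive, negative, positive).
#' @param n_cycles Number of scripted cycles.
#' @param seed Seed (telegraph initial state and flips).
#' @return Integer vector of 1 (positive state) / 0 (negative state).
#' @export
gen_state_sequence <- function(T = NULL, h = 0.01,
                               mode = c("telegraph", "scripted"),
                               cycle = c(50, 100, 50), n_cycles = 500,
                               seed = 1) {
  mode <- match.arg(mode)
  if (mode == "telegraph") {
    T <- check_count(T, "T")
    if (h < 0 || h > 1) abort("`h` must lie in [0, 1]")
    with_seed(seed, {
      s <- integer(T)
      s[1] <- stats::rbinom(1, 1, 0.5)
      if (T > 1) {
        flips <- stats::runif(T - 1) < h
        s[-1] <- (s[1] + cumsum(flips)) %% 2
      }
      s
    })
  } else {
    if (any(cycle <= 0)) abort("cycle lengths must be positive")
    one <- rep(c(1L, 0L, 1L), cycle)
    s <- rep(one, n_cycles)
    if (!is.null(T)) s <- s[seq_len(min(T, length(s)))]
    s
  }
}

#' Generate a bounded random-walk target trajectory
#'
#' Per coordinate, \eqn{\theta_{t+1} = \theta_t + N(0, \sigma^2)}, rounded
#' to the nearest integer and clipped to `[1, W]`.
#'
#' @param T Length.
#' @param sigma Walk standard deviation (1.2 low / 2.4 high uncertainty).
#' @param W Image width.
#' @param seed Seed.
#' @param start Starting `(row, col)`; defaults to the image center.
#' @return Integer `T x 2` matrix of `(row, col)` positions.
#' @export
gen_walk <- function(T, sigma, W = 32, seed = 1, start = NULL) {
  T <- check_count(T, "T")
  if (is.null(start)) start <- c((W + 1) / 2, (W + 1) / 2)
  with_seed(seed, {
    pos <- matrix(0, T, 2)
    cur <- start
    for (t in seq_len(T)) {
      if (t > 1) cur <- cur + stats::rnorm(2, 0, sigma)
      cur <- pmin(pmax(cur, 1), W)
      pos[t, ] <- round(cur)
    }
    colnames(pos) <- c("row", "col")
    pos
  })
}

#' Run the closed perception-action loop
#'
#' Simulates the full pipeline at each time step: draw the stimulus from
#' the current latent state, sparse-encode it, apply the shrinkage
#' nonlinearities at the currently selected thresholds, take the task
#' measurement, update the observer's belief, and select the thresholds for
#' the next step from the table using the predictive belief. In `"full"`
#' mode the thresholds are held at zero throughout, reproducing the
#' standard sparse code.
#'
#' @param context An `ac_context`.
#' @param table An `ac_threshold_table` (required in adaptive mode).
#' @param T Number of time steps.
#' @param seed Integer seed (environment, stimuli, measurement noise).
#' @param mode `"adaptive"` or `"full"`.
#' @param state_mode Binary tasks: `"scripted"` (default) or `"telegraph"`.
#' @param cycle,n_cycles Scripted environment blocks.
#' @param approx_predictive Use the low-hazard predictive shortcut in the
#'   binary belief update.
#' @param store_codes Keep the full `S`, `Z`, `Xi` matrices on the trace.
#' @return An `ac_trace`: a list with the per-step tibble `steps`, matrices
#'   `S`, `Z`, `Xi` (when stored), and metadata. The per-step feedback cost
#'   (standard deviation of the threshold vector, charged when it changes)
#'   is included as a `steps` column.
#' @export
run_closed_loop <- function(context, table = NULL, T = 1000, seed = 1,
                            mode = c("adaptive", "full"),
                            state_mode = c("scripted", "telegraph"),
                            cycle = c(50, 100, 50), n_cycles = NULL,
                            approx_predictive = FALSE, store_codes = TRUE) {
  mode <- match.arg(mode)
  state_mode <- match.arg(state_mode)
  T <- check_count(T, "T")
  if (mode == "adaptive") {
    if (is.null(table)) abort("adaptive mode needs a threshold table")
    if (table$task != context$task) abort("table was built for another task")
    if (!any(table$valid)) abort("threshold table has no valid entries")
  }
  switch(context$task,
         detection = run_loop_binary(context, table, T, seed, mode,
                                     state_mode, cycle, n_cycles,
                                     approx_predictive, store_codes),
         orientation = run_loop_binary(context, table, T, seed, mode,
                                       state_mode, cycle, n_cycles,
                                       approx_predictive, store_codes),
         localization = run_loop_localization(context, table, T, seed, mode,
                                              store_codes))
}

run_loop_binary <- function(context, table, T, seed, mode, state_mode,
                            cycle, n_cycles, approx_predictive,
                            store_codes) {
  W <- context$W
  if (is.null(n_cycles)) n_cycles <- ceiling(T / sum(cycle))
  states <- gen_state_sequence(T, h = context$h, mode = state_mode,
                               cycle = cycle, n_cycles = n_cycles,
                               seed = seed)
  # stimuli and codes for the whole trajectory (the environment is
  # exogenous, so encoding can be batched)
  if (context$task == "detection") {
    bg <- generate_patches(T, W, context$spectral_exponent, seed = seed + 1,
                           model = context$model)
    pos <- states == 1L
    if (any(pos)) {
      bg[pos, ] <- standardize(embed_object(bg[pos, , drop = FALSE],
                                            context$obj, context$gamma))
    }
    S <- encode(bg, context$dict, context$cfg)
    attr(S, "converged") <- NULL
  } else {
    idx <- with_seed(seed + 1, {
      i <- integer(T)
      i[states == 1L] <- sample(context$pools$H$eval, sum(states == 1L),
                                replace = TRUE)
      i[states == 0L] <- sample(context$pools$V$eval, sum(states == 0L),
                                replace = TRUE)
      i
    })
    S <- context$codes[idx, , drop = FALSE]
  }
  zeta <- with_seed(seed + 2, stats::rnorm(T, 0, context$sd_m))
  N <- context$dict$N
  Z <- matrix(0, T, N)
  Xi <- matrix(0, T, N)
  posterior <- predictive <- pred_logit <- m <- numeric(T)
  xi_index <- integer(T)
  belief <- 0.5
  xi_cur <- rep(0, N)
  if (mode == "adaptive") {
    xi_cur <- select_thresholds(table, belief)
    xi_index[1] <- attr(xi_cur, "index")
  }
  for (t in seq_len(T)) {
    Xi[t, ] <- xi_cur
    z <- if (mode == "full") S[t, ] else shrink(S[t, ], xi_cur, 10)
    Z[t, ] <- z
    m[t] <- binary_measurements(context, matrix(z, 1), zeta[t])
    upd <- update_binary_belief(belief, m[t], context$models,
                                positive = context$positive,
                                negative = context$negative,
                                h = context$h,
                                approx_predictive = approx_predictive)
    posterior[t] <- upd$posterior
    predictive[t] <- upd$predictive
    pred_logit[t] <- upd$predictive_logit
    belief <- upd$predictive
    if (mode == "adaptive" && t < T) {
      xi_cur <- select_thresholds(table, belief)
      xi_index[t + 1] <- attr(xi_cur, "index")
    }
  }
  fb <- feedback_cost_xi(Xi)
  steps <- tibble::tibble(
    t = seq_len(T), state = states, m = m, posterior = posterior,
    predictive = predictive, predictive_logit = pred_logit,
    activity = rowSums(abs(Z)),
    xi_index = xi_index, xi_changed = fb$changed, feedback_cost = fb$cost)
  new_trace(context$task, mode, steps, S, Z, Xi, store_codes,
            meta = list(seed = seed, state_mode = state_mode,
                        psi = table$psi %||% NA_real_))
}

run_loop_localization <- function(context, table, T, seed, mode,
                                  store_codes) {
  W <- context$W
  pos <- gen_walk(T, context$sigma_walk, W, seed = seed)
  frames <- generate_movie(T, W, drift = 1,
                           spectral_exponent = context$spectral_exponent,
                           seed = seed + 1, model = context$model)
  X <- t(vapply(seq_len(T), function(t) {
    superimpose_target(frames[t, ], context$cross, pos[t, ])
  }, numeric(W * W)))
  S <- encode(X, context$dict, context$cfg)
  attr(S, "converged") <- NULL
  N <- context$dict$N
  Z <- matrix(0, T, N)
  Xi <- matrix(0, T, N)
  m_row <- m_col <- mu_row <- mu_col <- pvar <- numeric(T)
  xi_index <- integer(T)
  belief <- list(mu = c((W + 1) / 2, (W + 1) / 2),
                 var = rep((W / 4)^2, 2))
  xi_cur <- rep(0, N)
  if (mode == "adaptive") {
    xi_cur <- select_thresholds(table, belief$mu)
    xi_index[1] <- attr(xi_cur, "index")
  }
  walk_var <- context$sigma_walk^2
  for (t in seq_len(T)) {
    Xi[t, ] <- xi_cur
    z <- if (mode == "full") S[t, ] else shrink(S[t, ], xi_cur, 10)
    Z[t, ] <- z
    mm <- cc_peak_cpp(context$cc0 + as.numeric(context$CM %*% z), W)
    m_row[t] <- mm[1]; m_col[t] <- mm[2]
    belief <- update_position_belief(belief, c(mm[1], mm[2]),
                                     noise_var = context$noise_var,
                                     walk_var = walk_var)
    mu_row[t] <- belief$mu[1]; mu_col[t] <- belief$mu[2]
    pvar[t] <- belief$pred_var[1]
    # predictive position distribution: static dynamics, variance inflated
    belief <- list(mu = belief$mu, var = belief$pred_var)
    if (mode == "adaptive" && t < T) {
      xi_cur <- select_thresholds(table, belief$mu)
      xi_index[t + 1] <- attr(xi_cur, "index")
    }
  }
  fb <- feedback_cost_xi(Xi)
  steps <- tibble::tibble(
    t = seq_len(T), state_row = pos[, 1], state_col = pos[, 2],
    m_row = m_row, m_col = m_col, mu_row = mu_row, mu_col = mu_col,
    pred_var = pvar,
    sq_error = (pos[, 1] - mu_row)^2 + (pos[, 2] - mu_col)^2,
    activity = rowSums(abs(Z)), xi_index = xi_index,
    xi_changed = fb$changed, feedback_cost = fb$cost)
  new_trace(context$task, mode, steps, S, Z, Xi, store_codes,
            meta = list(seed = seed, sigma_walk = context$sigma_walk,
                        psi = table$psi %||% NA_real_))
}

new_trace <- function(task, mode, steps, S, Z, Xi, store_codes, meta) {
  structure(list(task = task, mode = mode, steps = steps,
                 S = if (store_codes) S else NULL,
                 Z = if (store_codes) Z else NULL,
                 Xi = if (store_codes) Xi else NULL,
                 meta = meta),
            class = "ac_trace")
}

#' @export
print.ac_trace <- function(x, ...) {
  cat(sprintf(
    "<ac_trace> task = %s, mode = %s, T = %d (mean activity %.3g)\n",
    x$task, x$mode, nrow(x$steps), mean(x$steps$activity)))
  invisible(x)
}

# Per-step feedback cost from a threshold history matrix: the standard
# deviation of the threshold vector, charged at t = 1 and whenever any
# component changed from the previous step.
feedback_cost_xi <- function(Xi) {
  T <- nrow(Xi)
  changed <- logical(T)
  changed[1] <- TRUE
  if (T > 1) {
    changed[-1] <- rowSums(Xi[-1, , drop = FALSE] !=
                             Xi[-T, , drop = FALSE]) > 0
  }
  cost <- ifelse(changed, apply(Xi, 1, stats::sd), 0)
  list(changed = changed, cost = cost)
}

#' Feedback-activity cost of a trace
#'
#' @param trace An `ac_trace` (with stored thresholds) or a `T x N`
#'   threshold history matrix.
#' @return Tibble with per-step `t`, `changed`, `cost` and attribute
#'   `total`; `glance()` on a trace reports the mean.
#' @export
feedback_cost <- function(trace) {
  Xi <- if (inherits(trace, "ac_trace")) {
    if (is.null(trace$Xi)) abort("trace was stored without thresholds")
    trace$Xi
  } else trace
  fb <- feedback_cost_xi(Xi)
  out <- tibble::tibble(t = seq_len(nrow(Xi)), changed = fb$changed,
                        cost = fb$cost)
  attr(out, "total") <- sum(fb$cost)
  out
}
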