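#' Threshold-optimization configuration
#'
#' Controls the Rprop optimizer of the per-neuron thresholds and the
#' Monte-Carlo evaluation of the cost. Thresholds are parameterized as
#' `xi = a^2` so that positivity is automatic; gradients are numerical
#' central differences on `a`.
#'
#' @param psi Attentional resource constraint (activity weight; default 4).
#' @param n_mc Monte-Carlo samples per cost evaluation.
#' @param step_init,step_min,step_max Rprop step sizes.
#' @param eta_plus,eta_minus Rprop step multipliers.
#' @param max_iter Maximum Rprop iterations.
#' @param fd_step Finite-difference step on `a` (binary tasks).
#' @param fd_step_local Finite-difference step for localization: its
#'   inference term is piecewise constant in the correlation-peak position,
#'   and a probe this large is needed to cross peak-flip boundaries.
#' @param reltol Relative cost-change convergence tolerance over `window`
#'   accepted steps.
#' @param window Convergence window (accepted steps).
#' @param init_sd Standard deviation of the Gaussian initialization of `a`.
#' @param alpha Shrinkage smoothness constant.
#' @export
optim_config <- function(psi = 4, n_mc = 300, step_init = 0.1,
                         step_min = 1e-6, step_max = 1, eta_plus = 1.2,
                         eta_minus = 0.5, max_iter = 200, fd_step = 1e-3,
                         fd_step_local = 0.05, reltol = 1e-6, window = 10,
                         init_sd = 0.3, alpha = 10) {
  if (psi < 0) abort("`psi` must be >= 0")
  structure(list(psi = psi, n_mc = as.integer(n_mc), step_init = step_init,
                 step_max = step_max, step_min = step_min,
                 eta_plus = eta_plus, eta_minus = eta_minus,
                 max_iter = as.integer(max_iter), fd_step = fd_step,
                 fd_step_local = fd_step_local,
                 reltol = reltol, window = as.integer(window),
                 init_sd = init_sd, alpha = alpha),
            class = "ac_optim_config")
}

# Underflow guard for the Bernoulli computations: posteriors are handled on
# the logit scale, capped at the double-precision limit |logit| = 690.78
# (probability 1e-300), so extreme evidence never yields NaN while the guard
# stays purely numerical: a tighter cap (e.g. logit(1e-12) = 27.6) would
# saturate the per-sample symmetrized KL at moderate evidence and distort
# the cost optimum.
AC_LOGIT_CAP <- -stats::qlogis(1e-300)

clip_logit <- function(l) pmin(pmax(l, -AC_LOGIT_CAP), AC_LOGIT_CAP)

# Posterior logit of the positive state given measurements (vectorized).
binary_posterior_logit <- function(m, prior, models, positive, negative) {
  pp <- class_par(models, positive)
  pa <- class_par(models, negative)
  pr <- min(max(prior, 1e-12), 1 - 1e-12)
  clip_logit(qlogis(pr) +
               stats::dnorm(m, pp["mu"], pp["sigma"], log = TRUE) -
               stats::dnorm(m, pa["mu"], pa["sigma"], log = TRUE))
}

binary_posterior <- function(m, prior, models, positive, negative) {
  plogis(binary_posterior_logit(m, prior, models, positive, negative))
}

# Symmetrized KL between Bernoulli(p) and Bernoulli(q), vectorized; the
# logit-scale form (p - q) * (logit p - logit q) with capped logits.
sym_kl_bernoulli <- function(p, q) {
  lp <- clip_logit(qlogis(pmin(pmax(p, 0), 1)))
  lq <- clip_logit(qlogis(pmin(pmax(q, 0), 1)))
  (plogis(lp) - plogis(lq)) * (lp - lq)
}

sym_kl_bernoulli_logit <- function(lp, lq) {
  lp <- clip_logit(lp); lq <- clip_logit(lq)
  (plogis(lp) - plogis(lq)) * (lp - lq)
}

binary_measurements <- function(context, Z, zeta) {
  g <- if (context$task == "orientation") abs(Z) else Z
  w <- if (context$task == "orientation") context$d else context$w
  c0 <- if (context$task == "orientation") 0 else context$c0
  c0 + as.numeric(g %*% w) + zeta
}

#' Expected inference error of a threshold setting
#'
#' Mean (over the Monte-Carlo sample set) of the symmetrized
#' Kullback-Leibler divergence between the one-step posterior computed from
#' the compressed responses `z(xi)` and from the full code `z(xi = 0)`,
#' both starting from the same prior. Binary tasks use the exact Bernoulli
#' symmetrized KL; localization uses the closed-form equal-variance Gaussian
#' symmetrized KL per coordinate, summed.
#'
#' @param xi Threshold vector.
#' @param samples An `ac_cost_samples` from [draw_cost_samples()].
#' @param context The matching `ac_context`.
#' @param alpha Shrinkage smoothness constant.
#' @return Scalar expected inference error (0 exactly at `xi = 0`).
#' @export
symmetrized_kl_posteriors <- function(xi, samples, context, alpha = 10) {
  Z <- shrink(samples$S, xi, alpha)
  if (context$task %in% c("detection", "orientation")) {
    m1 <- binary_measurements(context, Z, samples$zeta)
    m0 <- binary_measurements(context, samples$S, samples$zeta)
    l1 <- binary_posterior_logit(m1, samples$prior, context$models,
                                 context$positive, context$negative)
    l0 <- binary_posterior_logit(m0, samples$prior, context$models,
                                 context$positive, context$negative)
    mean(sym_kl_bernoulli_logit(l1, l0))
  } else {
    W <- context$W
    M1 <- samples$n |> seq_len() |>
      vapply(function(i) context$cc0 + as.numeric(context$CM %*% Z[i, ]),
             numeric(W * W))
    M0 <- samples$n |> seq_len() |>
      vapply(function(i) context$cc0 +
               as.numeric(context$CM %*% samples$S[i, ]),
             numeric(W * W))
    v0 <- samples$prior_var
    sm2 <- context$noise_var
    post_var <- v0 * sm2 / (v0 + sm2)
    kl <- vapply(seq_len(samples$n), function(i) {
      pk1 <- cc_peak_cpp(M1[, i], W)
      pk0 <- cc_peak_cpp(M0[, i], W)
      mu1 <- (sm2 * samples$prior_mu + v0 * pk1) / (v0 + sm2)
      mu0 <- (sm2 * samples$prior_mu + v0 * pk0) / (v0 + sm2)
      sum((mu1 - mu0)^2) / post_var
    }, numeric(1))
    mean(kl)
  }
}

#' Total adaptation cost of a threshold setting
#'
#' The inference-error term of [symmetrized_kl_posteriors()] plus the
#' activity cost \eqn{\psi \sum_n \langle |z_n(\xi_n)| \rangle} over the
#' same samples.
#'
#' @inheritParams symmetrized_kl_posteriors
#' @param psi Attentional resource constraint.
#' @export
total_cost <- function(xi, samples, context, psi = 4, alpha = 10) {
  kl <- symmetrized_kl_posteriors(xi, samples, context, alpha)
  Z <- shrink(samples$S, xi, alpha)
  kl + psi * sum(colMeans(abs(Z)))
}

#' Optimize per-neuron thresholds for one belief state
#'
#' Minimizes the total adaptation cost over the thresholds by resilient
#' backpropagation (Rprop) with a numerically estimated gradient, on the
#' auxiliary variables `a` with `xi = a^2`, over a fixed Monte-Carlo sample
#' set (common random numbers). Proposed steps that fail to decrease the
#' cost (or make it non-finite) are rejected and the step sizes shrunk, so
#' the reported cost trace is non-increasing.
#'
#' @param samples An `ac_cost_samples` from [draw_cost_samples()].
#' @param context The matching `ac_context`.
#' @param cfg An [optim_config()].
#' @param seed Seed of the Gaussian initialization of `a`.
#' @param a_init Optional explicit initialization (overrides `seed`).
#' @return List of class `ac_xi_opt` with `xi`, `cost`, `trace`,
#'   `iterations`, `converged`.
#' @export
optimize_thresholds <- function(samples, context, cfg = optim_config(),
                                seed = 1, a_init = NULL) {
  N <- ncol(samples$S)
  if (is.null(a_init)) {
    a_init <- with_seed(seed, stats::rnorm(N, 0, cfg$init_sd))
  }
  res <- if (context$task %in% c("detection", "orientation")) {
    pp <- class_par(context$models, context$positive)
    pa <- class_par(context$models, context$negative)
    use_abs <- context$task == "orientation"
    w <- if (use_abs) context$d else context$w
    c0 <- if (use_abs) 0 else context$c0
    rprop_binary_cpp(samples$S, w, c0, samples$zeta,
                     pp["mu"], pp["sigma"], pa["mu"], pa["sigma"],
                     samples$prior, cfg$psi, cfg$alpha, use_abs, a_init,
                     cfg$fd_step, cfg$step_init, cfg$step_min, cfg$step_max,
                     cfg$eta_plus, cfg$eta_minus, cfg$max_iter, cfg$reltol,
                     cfg$window)
  } else {
    rprop_local_cpp(samples$S, context$CM, context$cc0,
                    samples$prior_mu[1], samples$prior_mu[2],
                    samples$prior_var, context$noise_var, cfg$psi,
                    cfg$alpha, context$W, a_init,
                    cfg$fd_step_local %||% cfg$fd_step,
                    cfg$step_init, cfg$step_min, cfg$step_max,
                    cfg$eta_plus, cfg$eta_minus, cfg$max_iter, cfg$reltol,
                    cfg$window)
  }
  structure(res, class = "ac_xi_opt")
}

#' @export
print.ac_xi_opt <- function(x, ...) {
  cat(sprintf(
    "<ac_xi_opt> %d thresholds, cost %.4g after %d iterations%s\n",
    length(x$xi), x$cost, x$iterations,
    if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

#' Build the table of optimal thresholds over a belief grid
#'
#' Optimizes one threshold vector per discretized belief state: `k` belief
#' probabilities \eqn{p_k = k/K} for the binary tasks (the grid of the
#' belief discretization, so a belief of 1 trains on a purely
#' positive-class set), or a `g x g` grid of positions linearly spaced in
#' `[1, W]` for localization. Training sets are drawn per grid point via
#' [draw_cost_samples()]. Grid points whose optimization fails are marked
#' invalid rather than aborting the table.
#'
#' @param context An `ac_context`.
#' @param k Number of belief bins (binary tasks).
#' @param g Grid side (localization; `g^2` points).
#' @param cfg An [optim_config()] (carries `psi` and `n_mc`).
#' @param seed Integer seed; per-point sample draws and initializations are
#'   derived from it.
#' @return An `ac_threshold_table` with the `K x N` matrix `xi`, the grid,
#'   per-point `cost` and `valid` flags, task and provenance metadata.
#' @export
build_threshold_table <- function(context, k = 32, g = 5,
                                  cfg = optim_config(), seed = 1) {
  N <- context$dict$N
  if (context$task %in% c("detection", "orientation")) {
    grid <- seq_len(k) / k
    K <- k
  } else {
    pts <- seq(1, context$W, length.out = g)
    grid <- as.matrix(expand.grid(row = pts, col = pts))
    K <- nrow(grid)
  }
  xi <- matrix(NA_real_, K, N)
  cost <- rep(NA_real_, K)
  valid <- logical(K)
  # Binary grids are optimized from the most informative belief downward,
  # warm-starting each point from its neighbor's optimum (next to a fresh
  # Gaussian start; the better of the two is kept). The cost surface has a
  # suppress-everything basin, and the homotopy lets the structured
  # solution found at high belief carry to beliefs where it remains
  # optimal but is hard to reach from a generic initialization.
  order_idx <- if (is.matrix(grid)) seq_len(K) else rev(seq_len(K))
  # localization: widen the training scatter by the grid-cell quantization
  # spread, so positions anywhere in a cell are covered by its entry
  spread_sd <- if (is.matrix(grid)) {
    spacing <- if (g > 1) (context$W - 1) / (g - 1) else context$W
    sqrt(context$sigma_walk^2 + spacing^2 / 12)
  } else NULL
  a_prev <- NULL
  for (i in order_idx) {
    belief <- if (is.matrix(grid)) grid[i, ] else grid[i]
    res <- tryCatch({
      smp <- draw_cost_samples(context, belief, n = cfg$n_mc,
                               seed = seed + 1000L * i,
                               spread_sd = spread_sd)
      best <- optimize_thresholds(smp, context, cfg,
                                  seed = seed + 1000L * i + 1L)
      if (!is.null(a_prev)) {
        warm <- optimize_thresholds(smp, context, cfg, a_init = a_prev)
        if (warm$cost < best$cost) best <- warm
      }
      best
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warn(sprintf("grid point %d failed: %s", i, conditionMessage(res)))
    } else {
      xi[i, ] <- res$xi
      cost[i] <- res$cost
      valid[i] <- TRUE
      a_prev <- res$a
    }
  }
  structure(list(xi = xi, grid = grid, task = context$task, psi = cfg$psi,
                 cost = cost, valid = valid, n_mc = cfg$n_mc, seed = seed),
            class = "ac_threshold_table")
}

#' @export
print.ac_threshold_table <- function(x, ...) {
  cat(sprintf(
    "<ac_threshold_table> task = %s, %d grid points x %d neurons (psi = %g)\n",
    x$task, nrow(x$xi), ncol(x$xi), x$psi))
  invisible(x)
}

#' Select the threshold vector matching a belief
#'
#' Binary tasks pick the grid probability nearest the current belief
#' (squared distance); localization picks the grid position nearest the
#' current point estimate (squared Euclidean distance). Ties go to the
#' lower grid index.
#'
#' @param table An `ac_threshold_table`.
#' @param belief Scalar probability, or `c(row, col)` point estimate.
#' @return Threshold vector (length `N`) with attribute `index`.
#' @export
select_thresholds <- function(table, belief) {
  if (nrow(table$xi) == 0) abort("empty threshold table")
  d2 <- if (is.matrix(table$grid)) {
    (table$grid[, 1] - belief[1])^2 + (table$grid[, 2] - belief[2])^2
  } else {
    (table$grid - belief[1])^2
  }
  d2[!table$valid] <- Inf
  i <- which.min(d2)
  out <- table$xi[i, ]
  attr(out, "index") <- i
  out
}

#' Static region-of-interest compression sweep
#'
#' The pedagogical static specialization of adaptive coding: for each value
#' of the attentional resource constraint, thresholds are optimized to
#' minimize the mean squared reconstruction error over the ROI pixels plus
#' \eqn{\psi \sum_n |z_n|}. At `psi = 0` the optimum reproduces the
#' full-code reconstruction; increasing `psi` suppresses population
#' activity while degrading out-of-ROI reconstruction first.
#'
#' @param image Pixel patch.
#' @param roi Logical or index vector over pixels (row-major), non-empty.
#' @param psi_list Values of the resource constraint to sweep.
#' @param dict An `ac_dictionary`.
#' @param cfg Sparse-coding settings.
#' @param ocfg An [optim_config()] (Rprop controls; `psi` ignored).
#' @param seed Initialization seed.
#' @return Tibble with one row per `psi`: `psi`, `activity` (total `|z|`),
#'   `snr_roi`, `snr_out`, `snr_full` (dB), and list-columns `xi`, `z`,
#'   `recon`.
#' @export
roi_compress <- function(image, roi, psi_list = c(0, 0.05, 0.2, 0.8),
                         dict, cfg = dict$config, ocfg = optim_config(),
                         seed = 1) {
  x <- as_patch_vector(image, dict$pca$W)
  roi_idx <- if (is.logical(roi)) which(roi) else as.integer(roi)
  if (length(roi_idx) == 0) abort("ROI mask is empty")
  s <- encode(x, dict, cfg)
  B <- t(atom_images(dict))                    # W^2 x N
  xc <- x - dict$pca$mean
  out_idx <- setdiff(seq_along(x), roi_idx)
  rows <- purrr::map(psi_list, function(psi) {
    if (psi == 0) {
      # inactive constraint: nothing penalizes activity, and shrinking can
      # only move the reconstruction away from the sparse-coding optimum,
      # so the optimum is the unshrunk code
      res <- list(xi = rep(0, dict$N), cost = 0)
    } else {
      a0 <- with_seed(seed, stats::rnorm(dict$N, 0, ocfg$init_sd))
      res <- rprop_roi_cpp(s, B[roi_idx, , drop = FALSE], xc[roi_idx], psi,
                           ocfg$alpha, cfg$sigma2, a0, ocfg$fd_step,
                           ocfg$step_init, ocfg$step_min, ocfg$step_max,
                           ocfg$eta_plus, ocfg$eta_minus, ocfg$max_iter,
                           ocfg$reltol, ocfg$window)
    }
    z <- shrink(s, res$xi, ocfg$alpha)
    recon <- decode(z, dict)
    tibble::tibble(
      psi = psi, activity = sum(abs(z)),
      snr_roi = snr_db(x, recon, mask = roi_idx),
      snr_out = if (length(out_idx)) snr_db(x, recon, mask = out_idx)
                else NA_real_,
      snr_full = snr_db(x, recon),
      cost = res$cost,
      xi = list(res$xi), z = list(z), recon = list(recon))
  })
  dplyr::bind_rows(rows)
}
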