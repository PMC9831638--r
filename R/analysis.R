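#' Signal-to-noise ratio of a reconstruction, in dB
#'
#' \eqn{10 \log_{10}(\sum_i x_i^2 / \sum_i (x_i - \hat{x}_i)^2)} over the
#' (optionally masked) pixels: the power-ratio form, equal to 20 log10 of
#' the amplitude ratio. A zero residual returns `Inf`, a zero signal
#' `-Inf`.
#'
#' @param x,xhat Patches (vectors or matching matrices).
#' @param mask Optional pixel index or logical mask.
#' @param const dB constant applied to the log power ratio (10 by default;
#'   20 treats the sums of squares as amplitudes).
#' @export
snr_db <- function(x, xhat, mask = NULL, const = 10) {
  x <- as_patch_vector(x); xhat <- as_patch_vector(xhat)
  if (length(x) != length(xhat)) abort("shape mismatch")
  if (!is.null(mask)) {
    x <- x[mask]; xhat <- xhat[mask]
  }
  sig <- sum(x^2); res <- sum((x - xhat)^2)
  if (res == 0) return(Inf)
  if (sig == 0) return(-Inf)
  const * log10(sig / res)
}

#' Pearson kurtosis
#'
#' Fourth standardized moment (Gaussian = 3), the sparsity index used for
#' response distributions. Zero-variance input returns `NA`.
#'
#' @param x Numeric vector.
#' @export
kurtosis <- function(x) {
  v <- mean((x - mean(x))^2)
  if (v == 0) return(NA_real_)
  mean((x - mean(x))^4) / v^2
}

#' Summary statistics of a response matrix
#'
#' Pooled-response kurtosis (sparsity), mean response magnitude per neuron,
#' and the per-step count of active neurons, where a neuron is active when
#' its magnitude exceeds 1% of its own maximum over the trace.
#'
#' @param Z `T x N` response matrix (or an `ac_trace`).
#' @param active_frac Activity threshold as a fraction of each neuron's
#'   maximum.
#' @return List with `kurtosis`, `mean_abs` (length `N`),
#'   `active_count` (length `T`), `active` (logical `T x N`).
#' @export
response_statistics <- function(Z, active_frac = 0.01) {
  if (inherits(Z, "ac_trace")) Z <- Z$Z
  if (nrow(Z) < 2) abort("need at least 2 time steps")
  mx <- apply(abs(Z), 2, max)
  thr <- active_frac * mx
  active <- sweep(abs(Z), 2, thr, ">")
  active[, mx == 0] <- FALSE
  list(kurtosis = kurtosis(as.numeric(Z)),
       mean_abs = colMeans(abs(Z)),
       active_count = rowSums(active),
       active = active)
}

#' Binary entropy in bits
#'
#' @param p Probability vector.
#' @export
binary_entropy <- function(p) {
  p <- pmin(pmax(p, 0), 1)
  h <- numeric(length(p))
  ok <- p > 0 & p < 1
  h[ok] <- -p[ok] * log2(p[ok]) - (1 - p[ok]) * log2(1 - p[ok])
  h
}

# Binary entropy computed from the belief logit: numerically faithful in
# the saturated regime, where the probability itself rounds to 0 or 1 in
# double precision and the entropy would degenerate to exactly zero.
binary_entropy_logit <- function(l) {
  al <- abs(l)
  p <- plogis(-al)                      # the smaller branch probability
  # -(1-p) log2(1-p) via log1p keeps precision for tiny p
  h <- -p * log2(pmax(p, .Machine$double.xmin)) - (1 - p) * log1p(-p) / log(2)
  h[al == 0] <- 1
  h
}

#' Population statistics by perceptual uncertainty
#'
#' Bins the time steps of a binary-task trace by the entropy of the
#' observer's prior belief (fixed thirds of a bit, or empirical deciles)
#' and aggregates per bin: mean population activity, mean reconstruction
#' SNR, mean active-neuron count, and the PCA cumulative explained-variance
#' curve of the responses (with the number of components needed for 90%
#' variance). Empty bins are dropped and flagged.
#'
#' @param trace An `ac_trace` from a binary task.
#' @param dict The `ac_dictionary` (for decoding; SNR needs stored codes).
#' @param bins `"deciles"` or `"thirds"` (edges 0, 1/3, 2/3, 1 bits).
#' @param stimuli Optional `T x W^2` stimulus matrix for SNR against the
#'   true input; defaults to decoding error against the full-code
#'   reconstruction.
#' @return Tibble, one row per non-empty bin, with list-column `cumvar`.
#' @export
uncertainty_profile <- function(trace, dict, bins = c("deciles", "thirds"),
                                stimuli = NULL) {
  bins <- match.arg(bins)
  if (!trace$task %in% c("detection", "orientation")) {
    abort("uncertainty binning applies to the binary tasks")
  }
  steps <- trace$steps
  T <- nrow(steps)
  # belief held before each stimulus; entropy from the logit when stored,
  # so saturated beliefs keep a well-defined uncertainty ordering
  u <- if ("predictive_logit" %in% names(steps)) {
    binary_entropy_logit(c(0, steps$predictive_logit[-T]))
  } else {
    binary_entropy(c(0.5, steps$predictive[-T]))
  }
  edges <- if (bins == "thirds") c(0, 1 / 3, 2 / 3, 1 + 1e-9) else {
    e <- unique(stats::quantile(u, probs = seq(0, 1, 0.1), names = FALSE))
    e[length(e)] <- e[length(e)] + 1e-9
    e
  }
  bin <- cut(u, edges, include.lowest = TRUE, labels = FALSE)
  ref <- if (is.null(stimuli)) decode(trace$S, dict) else stimuli
  rec <- decode(trace$Z, dict)
  stats_act <- response_statistics(trace$Z)
  rows <- purrr::map(sort(unique(bin)), function(b) {
    sel <- which(bin == b)
    Zb <- trace$Z[sel, , drop = FALSE]
    cumvar <- if (length(sel) > 2) {
      sv <- stats::prcomp(Zb, center = TRUE)$sdev^2
      cumsum(sv) / sum(sv)
    } else NA
    snr <- mean(vapply(sel, function(t) snr_db(ref[t, ], rec[t, ]),
                       numeric(1)))
    tibble::tibble(
      bin = b, n = length(sel),
      uncertainty = mean(u[sel]),
      mean_activity = mean(abs(Zb)),
      snr_db = snr,
      active_neurons = mean(stats_act$active_count[sel]),
      n90 = if (is.numeric(cumvar)) which(cumvar >= 0.9)[1] else NA_integer_,
      cumvar = list(cumvar))
  })
  dplyr::bind_rows(rows)
}

#' Correlation structure of task-modulated neurons
#'
#' Selects the `n_select` neurons most strongly modulated by the task (the
#' ratio of mean full-code activity to mean adaptive activity) and returns
#' their pairwise Pearson correlation matrices under the full and the
#' adaptive code over the same stimulus sequence. Constant rows give zero
#' correlations and are flagged.
#'
#' @param S_full `T x N` full-code matrix.
#' @param Z_adaptive `T x N` adaptive response matrix.
#' @param n_select Number of neurons.
#' @return List with `neurons`, `corr_full`, `corr_adaptive`, `flagged`.
#' @export
task_correlations <- function(S_full, Z_adaptive, n_select = 10) {
  if (!all(dim(S_full) == dim(Z_adaptive))) abort("shape mismatch")
  eps <- 1e-12
  ratio <- colMeans(abs(S_full)) / pmax(colMeans(abs(Z_adaptive)), eps)
  sel <- order(ratio, decreasing = TRUE)[seq_len(n_select)]
  corr_of <- function(M) {
    ok <- apply(M, 2, stats::sd) > 0
    C <- matrix(0, ncol(M), ncol(M))
    diag(C) <- 1
    if (any(ok)) C[ok, ok] <- stats::cor(M[, ok, drop = FALSE])
    list(C = C, flagged = !ok)
  }
  cf <- corr_of(S_full[, sel, drop = FALSE])
  ca <- corr_of(Z_adaptive[, sel, drop = FALSE])
  list(neurons = sel, corr_full = cf$C, corr_adaptive = ca$C,
       flagged = cf$flagged | ca$flagged)
}

#' Sinusoidal belief driver for repeated-presentation experiments
#'
#' A sine rescaled into `[0.1, 0.9]` completing `cycles` full periods over
#' `n` presentations: the canonical internal-belief fluctuation used for
#' the noise-correlation protocol of the binary tasks.
#'
#' @param n Presentations.
#' @param cycles Full periods.
#' @export
sine_belief_driver <- function(n, cycles = 5) {
  0.5 + 0.4 * sin(2 * pi * cycles * (seq_len(n) - 1) / n)
}

#' Belief-driven noise correlations at a fixed stimulus
#'
#' Encodes one fixed stimulus once, then generates `n_rep` responses whose
#' thresholds follow a fluctuating internal belief (a sine in `[0.1, 0.9]`
#' for binary tasks, a random walk for localization), adds independent
#' Gaussian noise of variance `noise_var` to every response, and returns
#' the resulting noise-correlation matrix and its scaled singular values,
#' together with the full-code (`xi = 0`) plus identical-noise baseline.
#'
#' @param stimulus Pixel patch.
#' @param context The task `ac_context`.
#' @param table The task's `ac_threshold_table`.
#' @param n_rep Presentations.
#' @param noise_var Additive response noise variance.
#' @param cycles Sine cycles (binary tasks).
#' @param seed Seed (noise and the localization belief walk).
#' @return List with `corr_adaptive`, `corr_full`, `sv_adaptive`,
#'   `sv_full` (singular values scaled by their maximum), `belief`.
#' @export
noise_correlation_experiment <- function(stimulus, context, table,
                                         n_rep = 1000, noise_var = 0.01,
                                         cycles = 5, seed = 1) {
  s <- encode(as_patch_vector(stimulus, context$W), context$dict,
              context$cfg)
  N <- length(s)
  belief <- if (context$task == "localization") {
    gen_walk(n_rep, context$sigma_walk, context$W, seed = seed + 1)
  } else {
    sine_belief_driver(n_rep, cycles)
  }
  Z <- matrix(0, n_rep, N)
  for (i in seq_len(n_rep)) {
    b <- if (is.matrix(belief)) belief[i, ] else belief[i]
    xi <- select_thresholds(table, b)
    Z[i, ] <- shrink(s, xi, 10)
  }
  noise <- with_seed(seed, matrix(stats::rnorm(2 * n_rep * N, 0,
                                               sqrt(noise_var)),
                                  2 * n_rep, N))
  Za <- Z + noise[seq_len(n_rep), ]
  Zf <- matrix(s, n_rep, N, byrow = TRUE) + noise[n_rep + seq_len(n_rep), ]
  corr0 <- function(M) {
    sds <- apply(M, 2, stats::sd)
    C <- matrix(0, ncol(M), ncol(M)); diag(C) <- 1
    ok <- sds > 0
    if (any(ok)) C[ok, ok] <- stats::cor(M[, ok, drop = FALSE])
    C
  }
  Ca <- corr0(Za); Cf <- corr0(Zf)
  sva <- svd(Ca, nu = 0, nv = 0)$d
  svf <- svd(Cf, nu = 0, nv = 0)$d
  list(corr_adaptive = Ca, corr_full = Cf,
       sv_adaptive = sva / max(sva), sv_full = svf / max(svf),
       belief = belief)
}

#' Mean absolute off-diagonal entry of a correlation matrix
#'
#' @param C Square correlation matrix.
#' @export
mean_abs_offdiag <- function(C) {
  mean(abs(C[upper.tri(C)]))
}

#' Orientation tuning curves under attended and unattended gains
#'
#' Probes every neuron with a bank of sinusoidal gratings (`n_orient`
#' orientations in `[0, 180)` crossed with frequencies and phases),
#' averaging response magnitudes over frequency and phase. Responses are
#' computed under two threshold conditions: "attended" (each neuron's
#' threshold taken from the table entry whose grid position is closest to
#' that neuron's receptive-field centroid) and "unattended" (thresholds
#' averaged over a completed simulation trace). Preferred orientation is
#' the curve's argmax; a centered Gaussian-times-amplitude fit is returned
#' per curve.
#'
#' @param dict An `ac_dictionary`.
#' @param table Localization `ac_threshold_table` (attended condition).
#' @param trace Localization `ac_trace` (unattended = time-averaged
#'   thresholds); alternatively pass `xi_unattended`.
#' @param cfg Sparse-coding settings for the probe encoding.
#' @param n_orient,frequencies,phases Grating bank.
#' @param xi_attended,xi_unattended Optional explicit threshold vectors.
#' @return Tibble, one row per neuron and condition: `neuron`, `condition`,
#'   `preferred`, `peak`, `amplitude`, `width`, `offset`, list-column
#'   `curve` (length `n_orient`), plus attribute `orientations`.
#' @export
tuning_curve_analysis <- function(dict, table = NULL, trace = NULL,
                                  cfg = sc_config(lambda = 0.1),
                                  n_orient = 32,
                                  frequencies = c(2, 4, 6, 8),
                                  phases = seq(0, 2 * pi, length.out = 9)[-9],
                                  xi_attended = NULL,
                                  xi_unattended = NULL) {
  W <- dict$pca$W
  if (is.null(xi_attended)) {
    if (is.null(table)) abort("need `table` or `xi_attended`")
    ctr <- atom_centroids(dict)
    xi_attended <- vapply(seq_len(dict$N), function(n) {
      select_thresholds(table, ctr[n, ])[n]
    }, numeric(1))
  }
  if (is.null(xi_unattended)) {
    if (is.null(trace)) abort("need `trace` or `xi_unattended`")
    xi_unattended <- colMeans(trace$Xi)
  }
  orientations <- seq(0, 180, length.out = n_orient + 1)[seq_len(n_orient)]
  bank <- expand.grid(orientation = orientations, frequency = frequencies,
                      phase = phases)
  G <- t(vapply(seq_len(nrow(bank)), function(i) {
    make_grating(bank$orientation[i], bank$frequency[i], bank$phase[i], W)
  }, numeric(W * W)))
  S <- encode(G, dict, cfg)
  curves_for <- function(xi, label) {
    Z <- abs(shrink(S, xi, 10))
    curve <- vapply(orientations, function(o) {
      colMeans(Z[bank$orientation == o, , drop = FALSE])
    }, numeric(dict$N))           # N x n_orient
    purrr::map_dfr(seq_len(dict$N), function(n) {
      cv <- curve[n, ]
      fit <- fit_centered_gaussian(cv, orientations)
      tibble::tibble(neuron = n, condition = label,
                     preferred = orientations[which.max(cv)],
                     peak = max(cv), amplitude = fit["amplitude"],
                     width = fit["width"], offset = fit["offset"],
                     silent = all(cv == 0), curve = list(cv))
    })
  }
  out <- dplyr::bind_rows(curves_for(xi_attended, "attended"),
                          curves_for(xi_unattended, "unattended"))
  attr(out, "orientations") <- orientations
  attr(out, "xi") <- list(attended = xi_attended,
                          unattended = xi_unattended)
  out
}

# Least-squares fit of amplitude * exp(-dtheta^2 / (2 width^2)) + offset to
# a tuning curve recentered on its preferred orientation (dtheta on the
# orientation circle). Grid search over width, linear in the rest.
fit_centered_gaussian <- function(curve, orientations) {
  pref <- orientations[which.max(curve)]
  d <- orientation_distance(orientations, pref)
  if (max(curve) == min(curve)) {
    return(c(amplitude = 0, width = NA_real_, offset = curve[1]))
  }
  best <- NULL
  for (wdt in seq(5, 90, by = 5)) {
    g <- exp(-d^2 / (2 * wdt^2))
    ft <- stats::lm(curve ~ g)
    rss <- sum(stats::residuals(ft)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, amplitude = unname(coef(ft)[2]),
                   offset = unname(coef(ft)[1]), width = wdt)
    }
  }
  c(amplitude = best$amplitude, width = best$width, offset = best$offset)
}

#' Temporal statistics of the gain (threshold) dynamics
#'
#' From a localization trace: pairwise correlations of the per-neuron
#' threshold series against the tuning similarity of the neuron pair
#' (correlation of absolute atom images), binned by tuning similarity, with
#' a shuffled-gain baseline (thresholds permuted across neurons post hoc);
#' activity correlations overlaid; mean normalized autocorrelation and
#' cross-correlation functions of the threshold series; and per-neuron
#' decay times (first lag at which the autocorrelation drops below 0.1).
#' Only neurons whose mean activity magnitude exceeds `include_frac` of the
#' population's maximal mean activity are included; constant-threshold
#' neurons are excluded.
#'
#' @param trace Localization `ac_trace`.
#' @param dict The `ac_dictionary`.
#' @param n_bins Tuning-similarity bins.
#' @param max_lag Autocorrelation lag range.
#' @param include_frac Inclusion threshold on mean activity.
#' @param seed Shuffle seed.
#' @return List with tibbles `binned` (tuning-similarity bins x gain /
#'   activity / shuffled-gain correlations), `decay` (per-neuron decay
#'   times), vectors `mean_acf`, `mean_ccf`, and the included neuron ids.
#' @export
gain_dynamics_analysis <- function(trace, dict, n_bins = 6, max_lag = 50,
                                   include_frac = 0.01, seed = 1) {
  Xi <- trace$Xi; Z <- trace$Z
  mean_act <- colMeans(abs(Z))
  keep <- mean_act > include_frac * max(mean_act)
  keep <- keep & apply(Xi, 2, stats::sd) > 0
  idx <- which(keep)
  if (length(idx) < 3) abort("too few modulated neurons in the trace")
  Xw <- Xi[, idx, drop = FALSE]
  Zw <- abs(Z[, idx, drop = FALSE])
  B <- abs(atom_images(dict))[idx, , drop = FALSE]
  tun <- stats::cor(t(B))
  gcorr <- stats::cor(Xw)
  acorr <- stats::cor(Zw)
  sh <- with_seed(seed, sample(ncol(Xw)))
  gshuf <- stats::cor(Xw[, sh, drop = FALSE])   # gains reassigned to
  ut <- upper.tri(tun)                          # random other neurons
  df <- tibble::tibble(tuning = tun[ut], gain = gcorr[ut],
                       activity = acorr[ut], gain_shuffled = gshuf[ut])
  df$bin <- cut(df$tuning, breaks = n_bins, labels = FALSE)
  binned <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(tuning = mean(.data$tuning),
                     gain = mean(.data$gain),
                     activity = mean(.data$activity),
                     gain_shuffled = mean(.data$gain_shuffled),
                     n = dplyr::n(), .groups = "drop")
  max_lag <- min(max_lag, nrow(Xw) - 2)
  acfs <- apply(Xw, 2, function(x) {
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  })
  decay <- apply(acfs, 2, function(a) {
    i <- which(a < 0.1)[1]
    if (is.na(i)) max_lag + 1L else i - 1L
  })
  n_pairs <- min(200, choose(length(idx), 2))
  pairs <- with_seed(seed + 1, {
    i <- sample(length(idx), n_pairs, replace = TRUE)
    j <- sample(length(idx), n_pairs, replace = TRUE)
    cbind(i, j)[i != j, , drop = FALSE]
  })
  ccfs <- vapply(seq_len(nrow(pairs)), function(kk) {
    stats::ccf(Xw[, pairs[kk, 1]], Xw[, pairs[kk, 2]],
               lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(2 * max_lag + 1))
  list(binned = binned, pairwise = df,
       decay = tibble::tibble(neuron = idx, decay_time = decay),
       mean_acf = rowMeans(acfs), mean_ccf = rowMeans(ccfs),
       lags = 0:max_lag, neurons = idx)
}

#' Population variability under a grating mixture and noise correlations
#' versus preferred-orientation difference
#'
#' Emulates the repeated presentation of a superposition of two gratings
#' (60 and 150 degrees, weights 1 and 0.2) while the gains follow the
#' threshold trajectory of an orientation-estimation simulation: per-trial
#' population response curves over preferred-orientation bins with
#' two-Gaussian mixture fits (component means fixed at 60 and 150 degrees,
#' common width 0.35 on the orientation axis in radians), and the
#' noise-correlation dependence on the difference in preferred orientation
#' from 12 grating orientations presented `n_rep` times each, with a
#' shuffled-gain baseline.
#'
#' @param dict An `ac_dictionary`.
#' @param trace Orientation `ac_trace` providing the gain trajectory.
#' @param cfg Sparse-coding settings for the probes.
#' @param n_trials Mixture presentations to fit.
#' @param n_rep Presentations per orientation in the noise-correlation
#'   protocol.
#' @param n_bins Preferred-orientation bins for the population curves.
#' @param noise_var Additive response noise variance.
#' @param seed Seed.
#' @return List with tibbles `trials` (per-trial fitted weights),
#'   `mean_fit`, `noise_corr` (Delta-preferred bins x mean correlation,
#'   unshuffled and shuffled), and `preferred` orientations.
#' @export
grating_mixture_analysis <- function(dict, trace,
                                     cfg = sc_config(lambda = 0.05),
                                     n_trials = 50, n_rep = 200,
                                     n_bins = 32, noise_var = 0.01,
                                     seed = 1) {
  W <- dict$pca$W
  tc <- tuning_curve_analysis(dict, cfg = cfg, n_orient = 16,
                              frequencies = c(2, 4), phases = c(0, pi / 2),
                              xi_attended = rep(0, dict$N),
                              xi_unattended = rep(0, dict$N))
  pref <- tc$preferred[tc$condition == "attended"]
  mix <- standardize(1 * make_grating(60, 4, 0, W) +
                       0.2 * make_grating(150, 4, 0, W))
  s_mix <- encode(mix, dict, cfg)
  Tn <- nrow(trace$Xi)
  pick <- with_seed(seed, sample(Tn, n_trials, replace = n_trials > Tn))
  bins <- seq(0, 180, length.out = n_bins + 1)
  bin_id <- cut(pref, bins, include.lowest = TRUE, labels = FALSE)
  bin_mid <- (bins[-1] + bins[-(n_bins + 1)]) / 2
  curve_of <- function(z) {
    vapply(seq_len(n_bins), function(b) {
      i <- which(bin_id == b)
      if (length(i) == 0) NA_real_ else mean(abs(z[i]))
    }, numeric(1))
  }
  # orientation axis in radians, so the fixed component width 0.35 is a
  # plausible tuning width (~20 degrees); on a unit-normalized axis the two
  # components would overlap almost completely
  xn <- bin_mid * pi / 180
  g1 <- stats::dnorm(xn, 60 * pi / 180, 0.35)
  g2 <- stats::dnorm(xn, 150 * pi / 180, 0.35)
  fit_mixture <- function(cv) {
    ok <- !is.na(cv)
    ft <- stats::lm(cv[ok] ~ g1[ok] + g2[ok])
    stats::setNames(coef(ft), c("b", "alpha1", "alpha2"))
  }
  trials <- purrr::map_dfr(seq_along(pick), function(k) {
    z <- shrink(s_mix, trace$Xi[pick[k], ], 10)
    cv <- curve_of(z)
    co <- fit_mixture(cv)
    tibble::tibble(trial = k, t = pick[k], alpha1 = co["alpha1"],
                   alpha2 = co["alpha2"], offset = co["b"],
                   curve = list(cv))
  })
  mean_curve <- colMeans(do.call(rbind, trials$curve), na.rm = TRUE)
  mean_fit <- fit_mixture(mean_curve)
  # noise correlations vs Delta preferred orientation
  oris <- seq(0, 180, length.out = 13)[1:12]
  probes <- t(vapply(oris, function(o) make_grating(o, 4, 0, W),
                     numeric(W * W)))
  S_pr <- encode(probes, dict, cfg)
  gain_idx <- with_seed(seed + 1, sample(Tn, 12 * n_rep, replace = TRUE))
  sh <- with_seed(seed + 2, sample(dict$N))
  nz <- with_seed(seed + 3,
                  matrix(stats::rnorm(12 * n_rep * dict$N, 0,
                                      sqrt(noise_var)),
                         12 * n_rep, dict$N))
  corr_sum <- corr_sum_sh <- matrix(0, dict$N, dict$N)
  kk <- 0
  for (o in seq_len(12)) {
    rows <- (o - 1) * n_rep + seq_len(n_rep)
    Zo <- t(vapply(rows, function(r) {
      shrink(S_pr[o, ], trace$Xi[gain_idx[r], ], 10)
    }, numeric(dict$N))) + nz[rows, ]
    Zs <- t(vapply(rows, function(r) {
      shrink(S_pr[o, ], trace$Xi[gain_idx[r], sh], 10)
    }, numeric(dict$N))) + nz[rows, ]
    corr_of0 <- function(M) {
      sds <- apply(M, 2, stats::sd)
      C <- matrix(0, ncol(M), ncol(M))
      ok <- sds > 0
      if (any(ok)) C[ok, ok] <- stats::cor(M[, ok, drop = FALSE])
      diag(C) <- 0
      C
    }
    corr_sum <- corr_sum + corr_of0(Zo)
    corr_sum_sh <- corr_sum_sh + corr_of0(Zs)
    kk <- kk + 1
  }
  Cm <- corr_sum / kk; Cs <- corr_sum_sh / kk
  dpref <- outer(pref, pref, function(a, b) {
    d <- (a - b) %% 180
    ifelse(d > 90, d - 180, d)
  })
  ut <- upper.tri(Cm)
  dedges <- seq(-90, 90, length.out = 13)
  db <- cut(dpref[ut], dedges, include.lowest = TRUE, labels = FALSE)
  noise_corr <- tibble::tibble(dpref = dpref[ut], corr = Cm[ut],
                               corr_shuffled = Cs[ut], bin = db) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(dpref = mean(.data$dpref),
                     corr = mean(.data$corr),
                     corr_shuffled = mean(.data$corr_shuffled),
                     n = dplyr::n(), .groups = "drop")
  list(trials = trials, mean_curve = mean_curve, mean_fit = mean_fit,
       noise_corr = noise_corr, preferred = pref, bin_mid = bin_mid)
}
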