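# Task contexts bundle everything the perceptual observer of one task needs:
# the dictionary and sparse-coding settings, measurement machinery, class
# models, and stimulus-generation parameters. They are consumed by the
# threshold optimizer, the table builder and the closed-loop simulator.

#' Build an object-detection task context
#'
#' Trains the observer of the object-detection task: simulates `n_train`
#' full-code measurements per state (object present at mixing coefficient
#' `gamma`, object absent) on 1/f backgrounds and fits the Gaussian class
#' models of the template-projection measurement.
#'
#' @param dict An `ac_dictionary`.
#' @param obj Object template (pixel vector), e.g. from [make_templates()].
#' @param cfg Sparse-coding settings (task default `lambda = 0.05`).
#' @param gamma Object mixing coefficient.
#' @param noise_var Measurement noise variance (default 0.01).
#' @param h Hazard rate of the telegraph environment.
#' @param spectral_exponent Background spectrum (`model = "spectral"`).
#' @param model Background texture model, as in [generate_patches()].
#' @param n_train Training measurements per state.
#' @param seed Integer seed.
#' @return An `ac_context` of task `"detection"`.
#' @export
detection_context <- function(dict, obj, cfg = sc_config(lambda = 0.05),
                              gamma = 0.2, noise_var = 0.01, h = 0.01,
                              spectral_exponent = 2,
                              model = c("leaves", "spectral"),
                              n_train = 1000, seed = 1) {
  model <- match.arg(model)
  W <- dict$pca$W
  dw <- detection_weights(dict, obj)
  bgA <- generate_patches(n_train, W, spectral_exponent, seed = seed,
                          model = model)
  # object-present frames are re-standardized: every stimulus the model sees
  # is a zero-mean unit-variance patch
  bgP <- standardize(embed_object(
    generate_patches(n_train, W, spectral_exponent, seed = seed + 1,
                     model = model),
    obj, gamma))
  SA <- encode(bgA, dict, cfg)
  SP <- encode(bgP, dict, cfg)
  sd_m <- sqrt(noise_var)
  m <- with_seed(seed + 2, {
    c(dw$c0 + as.numeric(SP %*% dw$w) + stats::rnorm(n_train, 0, sd_m),
      dw$c0 + as.numeric(SA %*% dw$w) + stats::rnorm(n_train, 0, sd_m))
  })
  models <- fit_class_models(m, rep(c("P", "A"), each = n_train))
  structure(list(task = "detection", dict = dict, cfg = cfg, obj = obj,
                 w = dw$w, c0 = dw$c0, gamma = gamma, noise_var = noise_var,
                 sd_m = sd_m, h = h, models = models,
                 positive = "P", negative = "A",
                 spectral_exponent = spectral_exponent, model = model,
                 W = W, seed = seed),
            class = "ac_context")
}

#' Build an orientation-estimation task context
#'
#' Encodes the corpus, discovers the horizontal and vertical stimulus
#' categories by k-means on log-ratio features, splits each category into
#' training and evaluation halves, learns the Fisher discriminant on the
#' training features, and fits Gaussian class models of the discriminant
#' measurement. The evaluation halves become the stimulus pools used in
#' simulations, so discriminant training never leaks into them.
#'
#' @param dict An `ac_dictionary`.
#' @param corpus Pixel patch matrix used for category discovery.
#' @param cfg Sparse-coding settings (task default `lambda = 0.05`).
#' @param noise_var Measurement noise variance (default 1e-4).
#' @param h Hazard rate.
#' @param k Number of k-means clusters.
#' @param train_frac Fraction of each category used for training.
#' @param balance_pools Activity-match the two categories by trimming
#'   extreme-activity members (at most 30% per category), so that total
#'   population activity carries no category signal under the full code.
#' @param seed Integer seed.
#' @return An `ac_context` of task `"orientation"`.
#' @export
orientation_context <- function(dict, corpus, cfg = sc_config(lambda = 0.05),
                                noise_var = 1e-4, h = 0.01, k = 9,
                                train_frac = 0.5, balance_pools = TRUE,
                                seed = 1) {
  corpus <- as_patch_matrix(corpus)
  S <- encode(corpus, dict, cfg)
  cats <- learn_orientation_categories(S, dict, k = k, seed = seed)
  if (length(cats$H) < 4 || length(cats$V) < 4) {
    abort("orientation categories too small; supply a larger corpus")
  }
  if (balance_pools) {
    # activity-match the two categories (trim extreme-activity members) so
    # that full-code population activity carries no category signal: the
    # stimulus-energy control that isolates belief-driven modulation
    act <- rowSums(abs(S))
    bal <- balance_by_activity(cats$H, cats$V, act)
    cats$H <- bal[[1]]
    cats$V <- bal[[2]]
  }
  split_idx <- function(idx, s) {
    tr <- with_seed(s, sample(idx, max(2, floor(train_frac * length(idx)))))
    list(train = tr, eval = setdiff(idx, tr))
  }
  hs <- split_idx(cats$H, seed + 11)
  vs <- split_idx(cats$V, seed + 12)
  # the discriminant is trained on the same representation the observer
  # projects: response magnitudes (log-ratio features serve clustering only)
  disc <- learn_discriminant(abs(S[hs$train, , drop = FALSE]),
                             abs(S[vs$train, , drop = FALSE]))
  sd_m <- sqrt(noise_var)
  mH <- as.numeric(abs(S[hs$train, , drop = FALSE]) %*% disc$d)
  mV <- as.numeric(abs(S[vs$train, , drop = FALSE]) %*% disc$d)
  m <- with_seed(seed + 13,
                 c(mH, mV) + stats::rnorm(length(mH) + length(mV), 0, sd_m))
  models <- fit_class_models(m, rep(c("H", "V"), c(length(mH), length(mV))))
  structure(list(task = "orientation", dict = dict, cfg = cfg,
                 discriminant = disc, d = disc$d, noise_var = noise_var,
                 sd_m = sd_m, h = h, models = models,
                 positive = "H", negative = "V",
                 categories = cats,
                 pools = list(
                   H = list(train = hs$train, eval = hs$eval),
                   V = list(train = vs$train, eval = vs$eval)),
                 corpus = corpus, codes = S, W = dict$pca$W, seed = seed),
            class = "ac_context")
}

# Trim members of the higher-activity set (largest activity first; or the
# smallest when its mean is lower) until the two sets' mean activities agree
# within 2% of their pooled mean, removing at most 30% per set.
balance_by_activity <- function(idx1, idx2, act, tol = 0.02,
                                max_trim = 0.3) {
  keep1 <- idx1
  keep2 <- idx2
  min1 <- ceiling((1 - max_trim) * length(idx1))
  min2 <- ceiling((1 - max_trim) * length(idx2))
  repeat {
    m1 <- mean(act[keep1]); m2 <- mean(act[keep2])
    if (abs(m1 - m2) <= tol * mean(act[c(keep1, keep2)])) break
    if (m1 > m2) {
      if (length(keep1) <= min1) break
      keep1 <- keep1[-which.max(act[keep1])]
    } else {
      if (length(keep2) <= min2) break
      keep2 <- keep2[-which.max(act[keep2])]
    }
  }
  list(keep1, keep2)
}

#' Build a target-localization task context
#'
#' Precomputes the per-atom cross-correlation maps that make the
#' localization measurement linear in the responses, and stores the
#' random-walk and measurement-noise parameters.
#'
#' @param dict An `ac_dictionary`.
#' @param cross 7x7 cross template.
#' @param cfg Sparse-coding settings (task default `lambda = 0.1`).
#' @param sigma_walk Random-walk standard deviation (1.2 low-uncertainty,
#'   2.4 high-uncertainty).
#' @param noise_var Measurement noise variance (default 1e-10, i.e.
#'   effectively vanishing).
#' @param spectral_exponent Background spectrum (`model = "spectral"`).
#' @param model Background texture model, as in [generate_patches()].
#' @return An `ac_context` of task `"localization"`.
#' @export
localization_context <- function(dict, cross, cfg = sc_config(lambda = 0.1),
                                 sigma_walk = 1.2, noise_var = 1e-10,
                                 spectral_exponent = 2,
                                 model = c("leaves", "spectral")) {
  model <- match.arg(model)
  ccb <- localization_cc_basis(dict, cross)
  structure(list(task = "localization", dict = dict, cfg = cfg,
                 cross = cross, CM = ccb$CM, cc0 = ccb$cc0,
                 sigma_walk = sigma_walk, noise_var = noise_var,
                 sd_m = sqrt(noise_var),
                 spectral_exponent = spectral_exponent, model = model,
                 W = dict$pca$W),
            class = "ac_context")
}

#' @export
print.ac_context <- function(x, ...) {
  cat(sprintf("<ac_context> task = %s, N = %d neurons (W = %d)\n",
              x$task, x$dict$N, x$W))
  invisible(x)
}

#' Draw the fixed Monte-Carlo sample set for one belief state
#'
#' Constructs the training set over which the threshold cost is averaged,
#' exactly as the predictive stimulus distribution of the task prescribes:
#' binary tasks mix the two stimulus classes in proportion `p / (1 - p)`
#' (a belief of 1 gives a purely positive-class set); localization scatters
#' the target around the believed position with the random-walk variance.
#' Measurement-noise draws are made once here and shared by the compressed
#' and full branches of the cost (common random numbers).
#'
#' @param context An `ac_context`.
#' @param belief Scalar probability (binary tasks) or `c(row, col)`
#'   (localization).
#' @param n Number of Monte-Carlo samples.
#' @param seed Integer seed.
#' @param spread_sd Localization only: standard deviation of the target
#'   scatter around the believed position; defaults to the walk standard
#'   deviation. Table building over a coarse belief grid widens this by the
#'   grid-cell quantization spread so that every position mapped to the
#'   grid point is covered by its training cloud.
#' @return List of class `ac_cost_samples` with the encoded codes `S`, the
#'   shared noise draws `zeta`, and the belief/prior description.
#' @export
draw_cost_samples <- function(context, belief, n = 300, seed = 1,
                              spread_sd = NULL) {
  n <- check_count(n, "n")
  W <- context$W
  out <- switch(
    context$task,
    detection = {
      p <- belief[1]
      n_pos <- round(p * n)
      bg <- generate_patches(n, W, context$spectral_exponent, seed = seed,
                             model = context$model)
      if (n_pos > 0) {
        bg[seq_len(n_pos), ] <- standardize(embed_object(
          bg[seq_len(n_pos), , drop = FALSE], context$obj, context$gamma))
      }
      S <- encode(bg, context$dict, context$cfg)
      zeta <- with_seed(seed + 1, stats::rnorm(n, 0, context$sd_m))
      list(S = S, zeta = zeta, prior = p, stimuli = bg)
    },
    orientation = {
      p <- belief[1]
      n_pos <- round(p * n)
      idx <- with_seed(seed, c(
        sample(context$pools$H$train, n_pos, replace = TRUE),
        sample(context$pools$V$train, n - n_pos, replace = TRUE)))
      S <- context$codes[idx, , drop = FALSE]
      zeta <- with_seed(seed + 1, stats::rnorm(n, 0, context$sd_m))
      list(S = S, zeta = zeta, prior = p, stimulus_idx = idx)
    },
    localization = {
      mu <- as.numeric(belief)
      if (is.null(spread_sd)) spread_sd <- context$sigma_walk
      pos <- with_seed(seed, cbind(
        stats::rnorm(n, mu[1], spread_sd),
        stats::rnorm(n, mu[2], spread_sd)))
      pos <- pmin(pmax(round(pos), 1), W)
      bg <- generate_patches(n, W, context$spectral_exponent,
                             seed = seed + 1, model = context$model)
      X <- t(vapply(seq_len(n), function(i) {
        superimpose_target(bg[i, ], context$cross, pos[i, ])
      }, numeric(W * W)))
      S <- encode(X, context$dict, context$cfg)
      list(S = S, zeta = NULL, prior_mu = mu,
           prior_var = spread_sd^2, positions = pos, stimuli = X)
    },
    abort(sprintf("unknown task '%s'", context$task)))
  structure(c(out, list(task = context$task, n = n, seed = seed)),
            class = "ac_cost_samples")
}
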