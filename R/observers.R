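#' Measurement noise specification
#'
#' @param variance Nonnegative variance of the additive Gaussian measurement
#'   noise. Task defaults: 0.01 (detection), 1e-10 (localization, i.e.
#'   sd 1e-5, effectively vanishing), 1e-4 (orientation).
#' @export
measurement_noise <- function(variance) {
  if (variance < 0) abort("noise variance must be >= 0")
  structure(list(variance = variance, sd = sqrt(variance)),
            class = "ac_noise")
}

# Linear form of the detection measurement: decode(z)' obj = c0 + w' z.
detection_weights <- function(dict, obj) {
  obj <- as.numeric(obj)
  list(w = as.numeric(dict$features %*% (t(dict$pca$rotation) %*% obj)),
       c0 = sum(dict$pca$mean * obj))
}

#' Object-detection measurement
#'
#' Projects the image linearly decoded from the responses onto the object
#' template and adds Gaussian noise:
#' \eqn{m = \hat{x}(z)^\top x_{obj} + \zeta}.
#'
#' @param z Response vector (length `N`).
#' @param dict An `ac_dictionary`.
#' @param obj Object template (pixel vector).
#' @param noise A [measurement_noise()] (default variance 0.01).
#' @return Scalar measurement (uses the session RNG for the noise draw).
#' @export
measure_detection <- function(z, dict, obj, noise = measurement_noise(0.01)) {
  dw <- detection_weights(dict, obj)
  dw$c0 + sum(dw$w * z) + if (noise$sd > 0) stats::rnorm(1, 0, noise$sd) else 0
}

#' Fit per-class Gaussian measurement models
#'
#' Sample mean and unbiased standard deviation of the measurement per class.
#' A class with (near-)zero variance gets a small floor applied to its
#' standard deviation and is flagged in the `floored` column.
#'
#' @param m Numeric measurements.
#' @param class Class labels (two or more classes, >= 2 samples each).
#' @param sd_floor Lower bound applied to class standard deviations.
#' @return Tibble with columns `class`, `mu`, `sigma`, `n`, `floored`.
#' @export
fit_class_models <- function(m, class, sd_floor = 1e-6) {
  tab <- table(class)
  if (any(tab < 2)) abort("each class needs at least 2 samples")
  cls <- names(tab)
  mu <- vapply(cls, function(k) mean(m[class == k]), numeric(1),
               USE.NAMES = FALSE)
  sg <- vapply(cls, function(k) stats::sd(m[class == k]), numeric(1),
               USE.NAMES = FALSE)
  tibble::tibble(class = cls, mu = mu, sigma = pmax(sg, sd_floor),
                 n = as.integer(tab), floored = sg < sd_floor)
}

# Extract (mu, sigma) for one class from a fit_class_models() tibble.
class_par <- function(models, cls) {
  i <- match(cls, models$class)
  if (is.na(i)) abort(sprintf("class '%s' not in the model table", cls))
  c(mu = unname(models$mu[i]), sigma = unname(models$sigma[i]))
}

#' Bayesian update of a binary belief
#'
#' One step of online inference over a telegraph (two-state) latent variable:
#' the posterior combines the prior with Gaussian class likelihoods of the
#' measurement (computed in log space, never NaN), and the predictive belief
#' propagates the posterior through the hazard-rate transition
#' \eqn{p' = (1-h)\,p + h\,(1-p)}. With `approx_predictive = TRUE` the
#' low-hazard shortcut `predictive = posterior` is used instead.
#'
#' @param prior Prior probability of the positive class, in `[0, 1]`.
#' @param m Scalar measurement.
#' @param models Class-model tibble from [fit_class_models()].
#' @param positive,negative Class labels of the positive / negative state.
#' @param h Hazard rate in `[0, 1]`.
#' @param approx_predictive Use the low-hazard approximation.
#' @return List with `posterior` and `predictive` probabilities.
#' @export
update_binary_belief <- function(prior, m, models, positive = "P",
                                 negative = "A", h = 0.01,
                                 approx_predictive = FALSE) {
  if (prior < 0 || prior > 1) abort("`prior` must lie in [0, 1]")
  if (h < 0 || h > 1) abort("`h` must lie in [0, 1]")
  pp <- class_par(models, positive)
  pa <- class_par(models, negative)
  pr <- min(max(prior, 1e-12), 1 - 1e-12)
  logit <- unname(qlogis(pr) +
    stats::dnorm(m, pp["mu"], pp["sigma"], log = TRUE) -
    stats::dnorm(m, pa["mu"], pa["sigma"], log = TRUE))
  posterior <- plogis(logit)
  predictive <- if (approx_predictive) posterior else {
    (1 - h) * posterior + h * (1 - posterior)
  }
  # logit of the predictive belief, kept meaningful where the probability
  # saturates in double precision
  pred_logit <- if (approx_predictive || h == 0) logit else {
    if (predictive > 0 && predictive < 1) qlogis(predictive) else
      sign(logit) * min(abs(logit), 700)
  }
  list(posterior = posterior, predictive = predictive,
       posterior_logit = logit, predictive_logit = pred_logit)
}

#' Cross-correlation peak localization measurement
#'
#' Decodes the stimulus from the responses, computes the "same"-size 2D
#' cross-correlation (zero padding) between the decoded image and the cross
#' template, and returns the 1-based `(row, col)` of its peak. Ties are
#' broken by the smallest row, then the smallest column.
#'
#' @param z Response vector.
#' @param dict An `ac_dictionary`.
#' @param cross 7x7 cross template.
#' @return Integer vector `c(row, col)`.
#' @export
measure_localization <- function(z, dict, cross) {
  img <- decode(z, dict)
  ccm <- cross_correlate(img, cross)
  W <- dict$pca$W
  out <- cc_peak_cpp(ccm, W)
  c(row = out[1], col = out[2])
}

# "Same"-size 2D cross-correlation of a row-major pixel image with a small
# template, zero-padded; returns a row-major vector over template-center
# positions.
cross_correlate <- function(image, template) {
  v <- as_patch_vector(image)
  W <- as.integer(round(sqrt(length(v))))
  img <- matrix(v, W, W, byrow = TRUE)
  half <- (nrow(template) - 1L) / 2L
  acc <- matrix(0, W, W)
  for (dr in -half:half) {
    for (dc in -half:half) {
      tv <- template[dr + half + 1L, dc + half + 1L]
      if (tv == 0) next
      rs <- max(1, 1 - dr):min(W, W - dr)
      cs <- max(1, 1 - dc):min(W, W - dc)
      acc[rs, cs] <- acc[rs, cs] + tv * img[rs + dr, cs + dc, drop = FALSE]
    }
  }
  as.vector(t(acc))
}

# Cross-correlation maps used by the localization observer: the map of a
# decoded image is cc0 + CM %*% z (linear in the responses).
localization_cc_basis <- function(dict, cross) {
  B <- atom_images(dict)                      # N x W^2
  CM <- apply(B, 1, function(a) cross_correlate(a, cross))   # W^2 x N
  cc0 <- cross_correlate(dict$pca$mean, cross)
  list(CM = CM, cc0 = cc0)
}

#' Conjugate Gaussian update of a position belief
#'
#' One coordinate-wise Kalman-style update for tracking a random-walk target
#' with Gaussian measurement noise: posterior
#' \eqn{\mu' = (\sigma_m^2 \mu + \sigma^2 m) / (\sigma^2 + \sigma_m^2)},
#' \eqn{\sigma'^2 = \sigma^2 \sigma_m^2 / (\sigma^2 + \sigma_m^2)}; the
#' next-step predicted measurement variance adds the walk variance.
#'
#' @param belief List with numeric `mu` and `var` (per coordinate).
#' @param m Measurement vector (same length as `mu`).
#' @param noise_var Measurement noise variance \eqn{\sigma_m^2}.
#' @param walk_var Random-walk increment variance added to the predictive
#'   variance.
#' @return List with posterior `mu`, `var`, and `pred_var`
#'   (`var + walk_var`).
#' @export
update_position_belief <- function(belief, m, noise_var, walk_var = 0) {
  if (any(belief$var <= 0)) abort("belief variances must be positive")
  s0 <- belief$var
  if (noise_var == 0) {
    mu <- as.numeric(m)
    v <- rep(0, length(s0))
  } else {
    mu <- (noise_var * belief$mu + s0 * m) / (s0 + noise_var)
    v <- s0 * noise_var / (s0 + noise_var)
  }
  list(mu = mu, var = v, pred_var = v + walk_var)
}

#' Discover orientation categories by unsupervised clustering
#'
#' Transforms each code into log-ratio features
#' \eqn{r_{n,t} = \log(|s_{n,t}| / \langle |s_{n,t}| \rangle_t)} (with an
#' epsilon floor inside the logarithm, since exact zeros occur in l1 codes),
#' clusters the feature vectors with k-means (`k = 9` by default), and
#' selects the horizontal and vertical clusters automatically: for each
#' cluster, the atoms whose mean feature exceeds 0 contribute their dominant
#' orientation to a circular average, and the clusters closest to 0 and 90
#' degrees are taken as H and V. Manual override via `h_cluster` /
#' `v_cluster`.
#'
#' @param S Code matrix (rows = patches).
#' @param dict The `ac_dictionary` (for atom orientations).
#' @param k Number of clusters.
#' @param seed Seed for k-means.
#' @param eps_frac Floor on `|s|` as a fraction of each neuron's maximum.
#' @param h_cluster,v_cluster Optional manual cluster indices.
#' @param retries Reseeding attempts on degenerate clusterings.
#' @return List with `H`, `V` (patch index vectors), `cluster` (assignment
#'   per patch), `features` (the r matrix), `orientation` (mean cluster
#'   orientation, degrees), `h_cluster`, `v_cluster`.
#' @export
learn_orientation_categories <- function(S, dict, k = 9, seed = 1,
                                         eps_frac = 1e-6, h_cluster = NULL,
                                         v_cluster = NULL, retries = 5) {
  R <- log_ratio_features(S, eps_frac)
  km <- NULL
  for (try in seq_len(retries)) {
    km <- tryCatch(
      with_seed(seed + try - 1,
                stats::kmeans(R, centers = k, nstart = 5, iter.max = 50)),
      error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) break
  }
  if (is.null(km)) abort("k-means failed to produce k non-empty clusters")
  orient <- atom_orientations(dict)
  cl_orient <- vapply(seq_len(k), function(ci) {
    mu <- colMeans(R[km$cluster == ci, , drop = FALSE])
    act <- which(mu > 0)
    if (length(act) == 0) act <- order(mu, decreasing = TRUE)[1:5]
    circ_mean_orientation(orient[act])
  }, numeric(1))
  dist_h <- orientation_distance(cl_orient, 0)
  dist_v <- orientation_distance(cl_orient, 90)
  if (is.null(h_cluster)) h_cluster <- which.min(dist_h)
  if (is.null(v_cluster)) {
    cand <- order(dist_v)
    v_cluster <- cand[cand != h_cluster][1]
  }
  list(H = which(km$cluster == h_cluster),
       V = which(km$cluster == v_cluster),
       cluster = km$cluster, features = R, orientation = cl_orient,
       h_cluster = h_cluster, v_cluster = v_cluster)
}

# log(|s| / mean_t |s|) with a per-neuron epsilon floor; silent neurons
# contribute a constant zero feature.
log_ratio_features <- function(S, eps_frac = 1e-6) {
  A <- abs(S)
  mx <- apply(A, 2, max)
  floor_n <- ifelse(mx > 0, eps_frac * mx, 1)
  A <- pmax(A, matrix(floor_n, nrow(S), ncol(S), byrow = TRUE))
  mn <- colMeans(A)
  log(A) - matrix(log(mn), nrow(S), ncol(S), byrow = TRUE)
}

# Circular mean of orientations on the 180-degree circle.
circ_mean_orientation <- function(theta_deg) {
  a <- theta_deg * pi / 90          # double the angle
  (atan2(mean(sin(a)), mean(cos(a))) * 90 / pi) %% 180
}

orientation_distance <- function(theta, ref) {
  d <- abs(theta - ref) %% 180
  pmin(d, 180 - d)
}

#' Fisher linear discriminant between two response classes
#'
#' Closed-form Fisher LDA on the log-ratio features of the two clusters:
#' direction \eqn{d = (\Sigma_w + \epsilon I)^{-1} (\mu_1 - \mu_2)} with the
#' pooled within-class covariance, ridge-regularized (singular covariances
#' are handled by the ridge and flagged).
#'
#' @param R1,R2 Feature matrices (rows = samples) of the two classes.
#' @param ridge Ridge added to the pooled covariance diagonal (relative to
#'   its mean diagonal).
#' @return List of class `ac_discriminant` with `d` (unit-norm weights),
#'   `threshold` (midpoint of projected class means), `accuracy` (training
#'   accuracy), `ridged` flag.
#' @export
learn_discriminant <- function(R1, R2, ridge = 1e-6) {
  if (nrow(R1) == 0 || nrow(R2) == 0) abort("both classes must be non-empty")
  mu1 <- colMeans(R1); mu2 <- colMeans(R2)
  C1 <- stats::cov(R1); C2 <- stats::cov(R2)
  n1 <- nrow(R1); n2 <- nrow(R2)
  Sw <- ((n1 - 1) * C1 + (n2 - 1) * C2) / max(n1 + n2 - 2, 1)
  scale <- mean(diag(Sw))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  ridged <- FALSE
  d <- tryCatch(solve(Sw, mu1 - mu2), error = function(e) NULL)
  if (is.null(d) || rcond_est(Sw) < 1e-12) {
    d <- solve(Sw + diag(ridge * scale, ncol(Sw)), mu1 - mu2)
    ridged <- TRUE
  }
  nd <- sqrt(sum(d^2))
  if (nd == 0) abort("discriminant direction has zero norm")
  d <- d / nd
  p1 <- as.numeric(R1 %*% d); p2 <- as.numeric(R2 %*% d)
  thr <- (mean(p1) + mean(p2)) / 2
  acc <- (sum(p1 > thr) + sum(p2 <= thr)) / (n1 + n2)
  structure(list(d = as.numeric(d), threshold = thr,
                 accuracy = max(acc, 1 - acc), ridged = ridged,
                 n = c(n1, n2)),
            class = "ac_discriminant")
}

rcond_est <- function(M) {
  tryCatch(rcond(M), error = function(e) 0)
}

#' @export
print.ac_discriminant <- function(x, ...) {
  cat(sprintf("<ac_discriminant> %d features, training accuracy %.3f%s\n",
              length(x$d), x$accuracy, if (x$ridged) " (ridged)" else ""))
  invisible(x)
}

#' Orientation-estimation measurement
#'
#' Projects the response magnitudes onto the discriminative vector and adds
#' Gaussian noise: \eqn{m = |z|^\top d + \zeta} (noise variance 1e-4 by
#' default).
#'
#' @param z Response vector.
#' @param discriminant An `ac_discriminant` (or a bare weight vector).
#' @param noise A [measurement_noise()].
#' @return Scalar measurement.
#' @export
measure_orientation <- function(z, discriminant,
                                noise = measurement_noise(1e-4)) {
  d <- if (inherits(discriminant, "ac_discriminant")) discriminant$d
       else as.numeric(discriminant)
  sum(abs(z) * d) + if (noise$sd > 0) stats::rnorm(1, 0, noise$sd) else 0
}
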