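#' Generate standardized 1/f-spectrum image patches
#'
#' Samples stationary Gaussian random fields with an isotropic power spectrum
#' proportional to \eqn{f^{-\gamma}} (default \eqn{\gamma = 2}, the classical
#' natural-image scaling) and standardizes each patch to zero mean and unit
#' variance. These textures stand in for a natural-image corpus: sparse
#' coding on such fields still yields localized, oriented features.
#'
#' @param n Number of patches.
#' @param W Patch width in pixels; patches are `W x W`.
#' @param spectral_exponent Exponent of the isotropic power spectrum
#'   (`model = "spectral"`).
#' @param seed Integer seed; output is a pure function of the seed.
#' @param coherence Leaves model only: probability that an element aligns
#'   with the patch's dominant orientation.
#' @param model `"spectral"` for the Gaussian random field, or `"leaves"`
#'   for the occlusion-based dead-leaves variant: opaque elliptical
#'   elements with scale-invariant sizes, random orientations and
#'   gray levels painted back-to-front. The leaves model shares the
#'   approximate 1/f power spectrum but is sparse and edge-dominated like
#'   natural movie frames, which matters wherever sparse-codeability of
#'   the corpus is part of the study conditions (Gaussian fields yield
#'   dense codes and non-localized features).
#' @return A numeric matrix with `n` rows, each a length-`W^2` patch in
#'   row-major order, with attribute `W`.
#' @export
generate_patches <- function(n, W = 32, spectral_exponent = 2, seed = 1,
                             model = c("spectral", "leaves"),
                             coherence = 0.7) {
  model <- match.arg(model)
  n <- check_count(n, "n")
  W <- check_count(W, "W", min = 4)
  X <- if (model == "spectral") {
    amp <- spectral_amplitude(W, spectral_exponent)
    with_seed(seed, {
      out <- matrix(0, n, W * W)
      for (i in seq_len(n)) {
        white <- matrix(stats::rnorm(W * W), W, W)
        field <- Re(stats::fft(stats::fft(white) * amp,
                               inverse = TRUE)) / (W * W)
        out[i, ] <- as.vector(t(field))
      }
      out
    })
  } else {
    with_seed(seed, {
      out <- matrix(0, n, W * W)
      for (i in seq_len(n)) {
        out[i, ] <- dead_leaves_patch(W, coherence = coherence)
      }
      out
    })
  }
  X <- standardize(X)
  attr(X, "W") <- W
  X
}

# One dead-leaves image: opaque ellipses, radii with density ~ r^-3
# (scale invariance gives the ~1/f^2 spectrum), uniform orientation,
# Gaussian gray levels, painted until the canvas is covered. Uses the
# session RNG (callers wrap in with_seed).
dead_leaves_patch <- function(W, r_min = 1.5, r_max = NULL,
                              aspect = c(0.2, 0.6), coherence = 0.7,
                              max_leaves = 400) {
  if (is.null(r_max)) r_max <- W / 2
  img <- matrix(NA_real_, W, W)
  rr <- matrix(seq_len(W), W, W)
  cc <- matrix(seq_len(W), W, W, byrow = TRUE)
  # per-patch dominant orientation: with probability `coherence` an element
  # aligns (with small jitter) to it, emulating the patch-level orientation
  # coherence of natural scenes
  th_patch <- stats::runif(1, 0, pi)
  # inverse-cdf sampling of r from density ~ r^-3 on [r_min, r_max]
  a2 <- r_min^-2; b2 <- r_max^-2
  for (i in seq_len(max_leaves)) {
    u <- stats::runif(1)
    r <- 1 / sqrt(a2 - u * (a2 - b2))
    th <- if (stats::runif(1) < coherence) {
      th_patch + stats::rnorm(1, 0, 0.15)
    } else stats::runif(1, 0, pi)
    asp <- stats::runif(1, aspect[1], aspect[2])
    ctr <- stats::runif(2, 0.5, W + 0.5)
    g <- stats::rnorm(1)
    dx <- cc - ctr[2]; dy <- rr - ctr[1]
    u1 <- dy * cos(th) + dx * sin(th)
    u2 <- -dy * sin(th) + dx * cos(th)
    inside <- (u1 / r)^2 + (u2 / (r * asp))^2 <= 1
    paint <- inside & is.na(img)
    img[paint] <- g
    if (!anyNA(img)) break
  }
  img[is.na(img)] <- 0
  as.vector(t(img))
}

# Amplitude filter (sqrt of the target power spectrum) on the FFT frequency
# grid; the DC component is zeroed so fields are mean-free before
# standardization.
spectral_amplitude <- function(W, spectral_exponent) {
  k <- c(0:(W %/% 2), -((W - W %/% 2 - 1):1))
  if (length(k) != W) k <- ((0:(W - 1) + W %/% 2) %% W) - W %/% 2
  fr <- matrix(k, W, W)
  fc <- matrix(k, W, W, byrow = TRUE)
  f <- sqrt(fr^2 + fc^2)
  amp <- ifelse(f == 0, 0, f^(-spectral_exponent / 2))
  amp
}

#' Generate a drifting correlated movie
#'
#' Frames are torus (circular) shifts of a single 1/f texture, drifting by
#' `drift` pixels per frame along image columns, each frame standardized.
#' Adjacent frames are therefore strongly correlated for small drifts and the
#' sequence is periodic with period `W / drift` frames for integer drifts.
#'
#' @param T Number of frames (>= 2).
#' @param W Frame width.
#' @param drift Pixels per frame (can be fractional; cumulative shift is
#'   rounded). Must not exceed `W`.
#' @param spectral_exponent Spectrum of the underlying texture.
#' @param seed Integer seed.
#' @param model Texture model, as in [generate_patches()].
#' @param blur Gaussian optical blur (pixels) applied to the base texture.
#' @return Matrix `T x W^2`, frames in rows, with attribute `W`.
#' @export
generate_movie <- function(T, W = 32, drift = 1, spectral_exponent = 2,
                           seed = 1, model = c("spectral", "leaves"),
                           blur = 1) {
  model <- match.arg(model)
  T <- check_count(T, "T", min = 2)
  W <- check_count(W, "W", min = 4)
  if (abs(drift) > W) abort("`drift` larger than the frame width")
  base <- generate_patches(1, W, spectral_exponent, seed = seed,
                           model = model)
  img <- matrix(base[1, ], W, W, byrow = TRUE)
  if (blur > 0) {
    # slight optical blur: movie frames are band-limited, and it keeps
    # adjacent shifted frames strongly correlated for any texture model
    k <- ((0:(W - 1) + W %/% 2) %% W) - W %/% 2
    f2 <- outer(k^2, k^2, "+")
    img <- Re(stats::fft(stats::fft(img) *
                           exp(-2 * pi^2 * blur^2 * f2 / W^2),
                         inverse = TRUE)) / (W * W)
    img <- matrix(standardize(as.numeric(img)), W, W)
  }
  out <- matrix(0, T, W * W)
  for (t in seq_len(T)) {
    sh <- round((t - 1) * drift) %% W
    shifted <- if (sh == 0) img else img[, c((sh + 1):W, 1:sh), drop = FALSE]
    out[t, ] <- as.vector(t(shifted))
  }
  attr(out, "W") <- W
  out
}

#' Object and target templates
#'
#' Builds the two task templates. The object template is a deterministic
#' procedural "tree": a compact lobed canopy on a short trunk, band-pass
#' filtered to its contour spatial frequencies (photographic object
#' templates are contour-dominated, and the mid band both survives the PCA
#' reduction and overlaps little with the 1/f-dominated low frequencies of
#' the backgrounds), confined to the silhouette support, standardized to
#' the patch scale and scaled by `object_contrast`. The localization target
#' is the 7x7 white cross: ones on its two 7-pixel arms (13 distinct
#' pixels) scaled by `cross_value`. Both intensities are free contrast
#' parameters on the standardized background scale; the defaults put both
#' tasks in a strongly discriminable regime.
#'
#' @param W Patch width (>= 8) for the object template.
#' @param seed Seed controlling the canopy outline.
#' @param cross_value Intensity of the cross arms (default 5).
#' @param object_contrast Root-mean-square contrast of the object template
#'   (default 12).
#' @param band Contour band as fractions of `W` (cycles per patch between
#'   `band[1] * W` and `band[2] * W`).
#' @return List with `object` (length `W^2` vector with mean 0 and pixel
#'   variance `object_contrast^2`, attribute `W`) and `cross` (7x7 matrix).
#' @export
make_templates <- function(W = 32, seed = 1, cross_value = 5,
                           object_contrast = 12, band = c(0.2, 0.4)) {
  W <- check_count(W, "W", min = 8)
  cross <- matrix(0, 7, 7)
  cross[4, ] <- cross_value
  cross[, 4] <- cross_value
  obj <- with_seed(seed, {
    # canopy: compact radial blob with seeded angular lobes + short trunk
    amp <- stats::runif(4, 0, 0.25)
    pha <- stats::runif(4, 0, 2 * pi)
    cy <- 0.45 * W; cx <- 0.5 * W; r0 <- 0.18 * W
    r <- matrix(seq_len(W), W, W)        # rows
    cc <- matrix(seq_len(W), W, W, byrow = TRUE)
    dy <- r - cy; dx <- cc - cx
    ang <- atan2(dx, dy)
    rad <- r0 * (1 + amp[1] * cos(2 * ang + pha[1]) +
                   amp[2] * cos(3 * ang + pha[2]) +
                   amp[3] * cos(5 * ang + pha[3]) +
                   amp[4] * cos(7 * ang + pha[4]))
    canopy <- sqrt(dx^2 + dy^2) <= rad
    trunk_w <- max(1, round(0.06 * W))
    trunk <- (abs(cc - cx) <= trunk_w / 2) & (r >= cy) & (r <= cy + 0.25 * W)
    f <- ifelse(canopy | trunk, 1, 0)
    # contour band-pass, confined to the silhouette support
    k <- ((0:(W - 1) + W %/% 2) %% W) - W %/% 2
    radf <- sqrt(matrix(k, W, W)^2 + matrix(k, W, W, byrow = TRUE)^2)
    mask <- radf >= band[1] * W & radf <= band[2] * W
    bp <- Re(stats::fft(stats::fft(f) * mask, inverse = TRUE)) / (W * W)
    as.vector(t(bp * (f > 0)))
  })
  obj <- object_contrast * standardize(obj)
  attr(obj, "W") <- W
  list(object = obj, cross = cross)
}

#' Linearly embed an object template into a patch
#'
#' Returns `(1 - gamma) * x + gamma * obj` elementwise; `gamma = 0.2` is the
#' default mixing coefficient of the object-detection task.
#'
#' @param x Patch (vector or matrix of patches in rows).
#' @param obj Object template vector of matching length.
#' @param gamma Mixing coefficient in `[0, 1]`.
#' @export
embed_object <- function(x, obj, gamma = 0.2) {
  if (gamma < 0 || gamma > 1) abort("`gamma` must lie in [0, 1]")
  obj <- as.numeric(obj)
  if (is.matrix(x)) {
    if (ncol(x) != length(obj)) abort("patch / template shape mismatch")
    (1 - gamma) * x + gamma * matrix(obj, nrow(x), length(obj), byrow = TRUE)
  } else {
    if (length(x) != length(obj)) abort("patch / template shape mismatch")
    (1 - gamma) * x + gamma * obj
  }
}

#' Superimpose the cross target on a frame
#'
#' The real-valued position is rounded to the nearest integer and clipped to
#' `[1, W]` per coordinate; the nonzero cross pixels then overwrite the
#' frame in the 7x7 neighborhood of the center (clipped at the borders).
#'
#' @param frame Patch vector (length `W^2`) or `W x W` matrix.
#' @param cross 7x7 cross template from [make_templates()].
#' @param position `(row, col)` real-valued target center.
#' @return Patch vector of length `W^2` with attribute `W`.
#' @export
superimpose_target <- function(frame, cross, position) {
  v <- as_patch_vector(frame)
  W <- as.integer(round(sqrt(length(v))))
  img <- matrix(v, W, W, byrow = TRUE)
  ctr <- pmin(pmax(round(position), 1), W)
  half <- (nrow(cross) - 1L) / 2L
  for (dr in -half:half) {
    for (dc in -half:half) {
      val <- cross[dr + half + 1L, dc + half + 1L]
      if (val == 0) next
      r <- ctr[1] + dr; c <- ctr[2] + dc
      if (r >= 1 && r <= W && c >= 1 && c <= W) img[r, c] <- val
    }
  }
  out <- as.vector(t(img))
  attr(out, "W") <- W
  out
}

#' Sinusoidal grating patch
#'
#' Generates a standardized sinusoidal grating. Orientation follows the
#' convention that 0 degrees gives horizontal stripes (each pixel row is
#' constant), increasing counter-clockwise; orientations are reduced modulo
#' 180 so that `theta` and `theta + 180` give identical patches.
#'
#' @param orientation Degrees.
#' @param frequency Cycles per patch; must be nonzero.
#' @param phase Radians.
#' @param W Patch width.
#' @return Length `W^2` standardized patch with attribute `W`.
#' @export
make_grating <- function(orientation, frequency, phase = 0, W = 32) {
  if (frequency == 0) abort("`frequency` must be nonzero (constant patch)")
  W <- check_count(W, "W", min = 4)
  th <- (orientation %% 180) * pi / 180
  r <- matrix(seq_len(W) - 1, W, W)
  cc <- matrix(seq_len(W) - 1, W, W, byrow = TRUE)
  u <- r * cos(th) + cc * sin(th)
  g <- sin(2 * pi * frequency * u / W + phase)
  out <- standardize(as.vector(t(g)))
  attr(out, "W") <- W
  out
}

#' PCA preprocessing of a patch corpus
#'
#' Mean-centers the corpus and retains the top `d` principal components,
#' mirroring the dimensionality reduction applied before dictionary
#' learning. The returned map carries the pixel mean, the orthonormal
#' component matrix and the per-component explained-variance fractions.
#'
#' @param patches Matrix of patches in rows.
#' @param d Target dimension (`d <= min(n - 1, W^2)` required).
#' @return An object of class `ac_pca` with elements `mean` (length `W^2`),
#'   `rotation` (`W^2 x d`, orthonormal columns), `d`, `W`, `var_explained`,
#'   and `scores` (`n x d` coordinates of the input corpus).
#' @export
preprocess_corpus <- function(patches, d) {
  patches <- as_patch_matrix(patches)
  d <- check_count(d, "d")
  p <- ncol(patches)
  if (d > p) abort("`d` exceeds the pixel dimension")
  if (d > nrow(patches)) abort("`d` exceeds the number of patches")
  pc <- stats::prcomp(patches, center = TRUE, scale. = FALSE, rank. = d)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  map <- structure(
    list(mean = as.numeric(pc$center),
         rotation = pc$rotation[, seq_len(d), drop = FALSE],
         d = d, W = as.integer(round(sqrt(p))),
         var_explained = ve[seq_len(d)]),
    class = "ac_pca")
  map$scores <- pc$x[, seq_len(d), drop = FALSE]
  map
}

#' @export
print.ac_pca <- function(x, ...) {
  cat(sprintf("<ac_pca> %d pixels -> %d components (%.1f%% variance)\n",
              length(x$mean), x$d, 100 * sum(x$var_explained)))
  invisible(x)
}

# Project pixel patches (rows) into the reduced space.
pca_project <- function(map, X) {
  X <- as_patch_matrix(X)
  sweep(X, 2, map$mean) %*% map$rotation
}

# Back-project reduced coordinates (rows) to pixel space.
pca_backproject <- function(map, Y) {
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
  Y %*% t(map$rotation) + matrix(map$mean, nrow(Y), length(map$mean),
                                 byrow = TRUE)
}
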