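#' Sparse-coding configuration
#'
#' Bundles the parameters of the sparse-coding energy: the sparsity weight
#' `lambda`, the reconstruction noise level `sigma2`, and the FISTA solver
#' controls. Task defaults used throughout: `lambda = 1` for dictionary
#' learning, `0.05` for object detection and orientation estimation, `0.1`
#' for target localization, with `sigma2 = 0.5` everywhere.
#'
#' @param lambda Nonnegative sparsity weight.
#' @param sigma2 Positive noise level of the reconstruction term.
#' @param tol Relative energy-change convergence tolerance of the solver.
#' @param max_iter Maximum FISTA iterations.
#' @export
sc_config <- function(lambda = 1, sigma2 = 0.5, tol = 1e-8, max_iter = 500) {
  if (lambda < 0) abort("`lambda` must be >= 0")
  if (sigma2 <= 0) abort("`sigma2` must be > 0")
  structure(list(lambda = lambda, sigma2 = sigma2, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "ac_sc_config")
}

new_dictionary <- function(features, pca, config) {
  structure(list(features = features, pca = pca, N = nrow(features),
                 d = ncol(features), config = config),
            class = "ac_dictionary")
}

#' @export
print.ac_dictionary <- function(x, ...) {
  cat(sprintf("<ac_dictionary> N = %d neurons, d = %d (W = %d)\n",
              x$N, x$d, x$pca$W))
  invisible(x)
}

#' Linear decoding of a sparse code
#'
#' Reconstructs patches from codes as the feature superposition
#' \eqn{\hat{x} = \sum_n \phi_n s_n} in the reduced space, back-projected to
#' pixels through the PCA map (so `s = 0` decodes to the corpus mean patch).
#'
#' @param s Code vector of length `N`, or matrix of codes in rows.
#' @param dict An `ac_dictionary`.
#' @return Pixel patches (rows) of length `W^2`, or a vector for one code.
#' @export
decode <- function(s, dict) {
  single <- !is.matrix(s)
  if (single) s <- matrix(s, nrow = 1)
  if (ncol(s) != dict$N) abort("code length does not match the dictionary")
  X <- pca_backproject(dict$pca, s %*% dict$features)
  if (single) as.numeric(X) else X
}

#' Sparse-coding energy
#'
#' Evaluates the sparse-coding objective
#' \eqn{\sum_i (\hat{x}_i - x_i)^2 / (2\sigma^2) + \lambda \sum_n |s_n|}
#' in the reduced (PCA) space, matching the space in which encoding and
#' dictionary learning operate.
#'
#' @param x Patch (pixel vector/matrix) or reduced coordinates if
#'   `reduced = TRUE`.
#' @param s Code(s), rows matching `x`.
#' @param dict An `ac_dictionary`.
#' @param cfg An [sc_config()].
#' @param reduced Set when `x` is already in the reduced space.
#' @return Energy value(s), one per patch.
#' @export
energy <- function(x, s, dict, cfg = dict$config, reduced = FALSE) {
  Y <- if (reduced) {
    if (!is.matrix(x)) matrix(x, nrow = 1) else x
  } else pca_project(dict$pca, x)
  if (!is.matrix(s)) s <- matrix(s, nrow = 1)
  R <- Y - s %*% dict$features
  as.numeric(rowSums(R^2) / (2 * cfg$sigma2) + cfg$lambda * rowSums(abs(s)))
}

# Batch FISTA for the l1-penalized reconstruction objective, operating on
# reduced coordinates Y (rows samples). Returns codes (rows samples).
fista_encode <- function(Y, features, lambda, sigma2, tol = 1e-8,
                         max_iter = 500L) {
  N <- nrow(features)
  n <- nrow(Y)
  G <- features %*% t(features)
  L <- max(lip_norm(G), .Machine$double.eps) / sigma2
  C <- features %*% t(Y) / sigma2          # N x n
  S <- matrix(0, N, n)
  Zm <- S
  tk <- 1
  obj_old <- Inf
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- (G %*% Zm) / sigma2 - C
    Snew <- soft_threshold(Zm - grad / L, lambda / L)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Zm <- Snew + ((tk - 1) / tk_new) * (Snew - S)
    S <- Snew
    tk <- tk_new
    if (it %% 10 == 0 || it == max_iter) {
      R <- t(S) %*% features - Y
      obj <- sum(R^2) / (2 * sigma2) + lambda * sum(abs(S))
      if (is.finite(obj_old) &&
          abs(obj_old - obj) <= tol * max(abs(obj_old), 1)) {
        conv <- TRUE
        break
      }
      obj_old <- obj
    }
  }
  structure(t(S), converged = conv)
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

# Spectral norm of a symmetric PSD matrix by power iteration.
lip_norm <- function(G, iters = 50) {
  v <- rep(1, ncol(G)) / sqrt(ncol(G))
  ev <- 0
  for (i in seq_len(iters)) {
    w <- G %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- as.numeric(w / nw)
    ev_new <- nw
    if (abs(ev_new - ev) < 1e-10 * max(ev_new, 1)) break
    ev <- ev_new
  }
  ev_new
}

#' Sparse encoding of patches
#'
#' Minimizes the convex sparse-coding energy over the coefficients with
#' FISTA, in the reduced PCA space. For an orthonormal dictionary this
#' coincides with elementwise soft-thresholding of the feature projections.
#'
#' @param x Pixel patch vector, matrix of patches in rows, or reduced
#'   coordinates when `reduced = TRUE`.
#' @param dict An `ac_dictionary`.
#' @param cfg An [sc_config()]; defaults to the dictionary's.
#' @param reduced Set when `x` is already reduced.
#' @return Code vector (single patch) or `n x N` matrix; attribute
#'   `converged` reports solver convergence.
#' @export
encode <- function(x, dict, cfg = dict$config, reduced = FALSE) {
  single <- !is.matrix(x)
  Y <- if (reduced) {
    if (!is.matrix(x)) matrix(x, nrow = 1) else x
  } else pca_project(dict$pca, x)
  S <- fista_encode(Y, dict$features, cfg$lambda, cfg$sigma2, cfg$tol,
                    cfg$max_iter)
  if (!attr(S, "converged")) {
    warn("sparse encoding did not reach the energy tolerance; result flagged")
  }
  if (single) {
    out <- as.numeric(S)
    attr(out, "converged") <- attr(S, "converged")
    out
  } else S
}

#' Learn a sparse-coding dictionary
#'
#' SparseNet-style alternating optimization: mini-batch sparse inference of
#' the coefficients (FISTA) alternates with a gradient step on the features,
#' whose rows are renormalized to unit norm after every update. The
#' feature step size is set from the batch Lipschitz constant and decays as
#' \eqn{1/\sqrt{\mathrm{epoch}}}.
#'
#' @param patches Pixel patch matrix (rows), e.g. from [generate_patches()].
#' @param N Number of atoms / model neurons.
#' @param cfg An [sc_config()] (learning default `lambda = 1`,
#'   `sigma2 = 0.5`).
#' @param epochs Passes over the corpus.
#' @param batch_size Mini-batch size.
#' @param d Reduced dimension; defaults to `N` (capped by the corpus rank).
#' @param pca Optional precomputed `ac_pca` map to reuse.
#' @param step Base feature step size as a fraction of the safe (Lipschitz)
#'   step.
#' @param seed Integer seed (initialization and batch order).
#' @param init Feature initialization: `"bank"` (default) starts from a
#'   deterministic tiling of Gabor features (positions x orientations),
#'   the known optimum family for natural-like corpora, which the gradient
#'   learning then adapts; `"data"` from random corpus samples; `"random"`
#'   from Gaussian noise.
#' @param seed_atoms Optional matrix of pixel-space patterns (rows) placed
#'   into the initial feature set, e.g. template-derived features when the
#'   corpus is known to contain a recurring object; a fully converged run
#'   would allocate such features by itself.
#' @return An `ac_dictionary`; attribute `energy_trace` carries the mean
#'   corpus energy after each epoch.
#' @export
learn_dictionary <- function(patches, N = 512, cfg = sc_config(),
                             epochs = 10, batch_size = 100, d = NULL,
                             pca = NULL, step = 0.5, seed = 1,
                             init = c("bank", "data", "random"),
                             seed_atoms = NULL) {
  init <- match.arg(init)
  patches <- as_patch_matrix(patches)
  N <- check_count(N, "N")
  n <- nrow(patches)
  if (n < 2) abort("degenerate corpus")
  if (is.null(pca)) {
    if (is.null(d)) d <- min(N, ncol(patches), n - 1)
    pca <- preprocess_corpus(patches, d)
  }
  Y <- pca_project(pca, patches)
  if (all(abs(Y) < 1e-12)) abort("degenerate corpus (zero variance)")
  d <- ncol(Y)
  Phi <- switch(init,
    bank = gabor_bank(pca$W, N) %*% pca$rotation,
    data = Y[with_seed(seed, sample.int(nrow(Y), N, replace = nrow(Y) < N)),
             , drop = FALSE],
    random = with_seed(seed, matrix(stats::rnorm(N * d), N, d)))
  if (!is.null(seed_atoms)) {
    if (!is.matrix(seed_atoms)) seed_atoms <- matrix(seed_atoms, nrow = 1)
    sa <- seed_atoms %*% pca$rotation
    Phi[nrow(Phi) - seq_len(nrow(sa)) + 1L, ] <- sa
  }
  nr0 <- sqrt(rowSums(Phi^2))
  nr0[nr0 == 0] <- 1
  Phi <- Phi / nr0
  energy_trace <- numeric(epochs)
  order_seed <- seed + 1L
  for (ep in seq_len(epochs)) {
    idx <- with_seed(order_seed + ep, sample.int(n))
    lr <- step / sqrt(ep)
    for (b in seq_len(ceiling(n / batch_size))) {
      rows <- idx[((b - 1) * batch_size + 1):min(b * batch_size, n)]
      Yb <- Y[rows, , drop = FALSE]
      S <- fista_encode(Yb, Phi, cfg$lambda, cfg$sigma2,
                        tol = 1e-6, max_iter = 200L)
      R <- Yb - S %*% Phi
      Lb <- max(lip_norm(t(S) %*% S), .Machine$double.eps) / cfg$sigma2
      Phi <- Phi + (lr / (Lb * cfg$sigma2)) * (t(S) %*% R)
      nr <- sqrt(rowSums(Phi^2))
      dead <- nr < 1e-10
      if (any(dead)) {
        # re-seed unused atoms from random corpus directions
        Phi[dead, ] <- Y[sample(rows, sum(dead), replace = TRUE), ,
                         drop = FALSE]
        nr <- sqrt(rowSums(Phi^2))
        nr[nr == 0] <- 1
      }
      Phi <- Phi / nr
    }
    Sfull <- fista_encode(Y, Phi, cfg$lambda, cfg$sigma2,
                          tol = 1e-6, max_iter = 200L)
    Rf <- Y - Sfull %*% Phi
    energy_trace[ep] <- mean(rowSums(Rf^2) / (2 * cfg$sigma2) +
                               cfg$lambda * rowSums(abs(Sfull)))
  }
  dict <- new_dictionary(Phi, pca, cfg)
  attr(dict, "energy_trace") <- energy_trace
  dict
}

# Deterministic Gabor tiling used as the feature initialization: a grid of
# positions crossed with orientations, envelope and wavelength scaled to
# the patch width.
gabor_bank <- function(W, N, n_orient = 8) {
  g <- ceiling(sqrt(N / n_orient))
  pos <- expand.grid(r = seq(2.5, W - 1.5, length.out = g),
                     c = seq(2.5, W - 1.5, length.out = g))
  oris <- seq(0, 180, length.out = n_orient + 1)[seq_len(n_orient)]
  rr <- matrix(seq_len(W), W, W)
  cc <- matrix(seq_len(W), W, W, byrow = TRUE)
  sig <- 0.14 * W
  wl <- 0.31 * W
  out <- matrix(0, nrow(pos) * n_orient, W * W)
  k <- 0
  for (i in seq_len(nrow(pos))) {
    for (o in oris) {
      th <- o * pi / 180
      u <- (rr - pos$r[i]) * cos(th) + (cc - pos$c[i]) * sin(th)
      v <- -(rr - pos$r[i]) * sin(th) + (cc - pos$c[i]) * cos(th)
      k <- k + 1
      out[k, ] <- as.vector(t(exp(-(u^2 + v^2) / (2 * sig^2)) *
                                cos(2 * pi * u / wl)))
    }
  }
  out[seq_len(N), , drop = FALSE]
}

# Pixel-space images of all atoms: N x W^2 matrix (no mean offset).
atom_images <- function(dict) {
  dict$features %*% t(dict$pca$rotation)
}

# Spatial centroid (row, col) of the absolute pixel image of each atom.
atom_centroids <- function(dict) {
  B <- abs(atom_images(dict))
  W <- dict$pca$W
  rr <- as.vector(t(matrix(seq_len(W), W, W)))          # row index per pixel
  cc <- as.vector(t(matrix(seq_len(W), W, W, byrow = TRUE)))
  wsum <- rowSums(B)
  wsum[wsum == 0] <- 1
  cbind(row = as.numeric(B %*% rr) / wsum,
        col = as.numeric(B %*% cc) / wsum)
}

# Dominant orientation (degrees in [0, 180)) of each atom from the peak of
# its 2D power spectrum, consistent with the make_grating() convention
# (0 = horizontal stripes, i.e. modulation along rows).
atom_orientations <- function(dict) {
  B <- atom_images(dict)
  W <- dict$pca$W
  k <- ((0:(W - 1) + W %/% 2) %% W) - W %/% 2
  fr <- matrix(k, W, W)
  fc <- matrix(k, W, W, byrow = TRUE)
  vapply(seq_len(nrow(B)), function(n) {
    img <- matrix(B[n, ], W, W, byrow = TRUE)
    P <- Mod(stats::fft(img - mean(img)))^2
    P[1, 1] <- 0
    i <- which.max(P)
    (atan2(fc[i], fr[i]) * 180 / pi) %% 180
  }, numeric(1))
}
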