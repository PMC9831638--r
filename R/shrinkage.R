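#' Smooth shrinkage nonlinearity
#'
#' Applies the smooth, differentiable shrinkage operator
#' \deqn{z = \mathrm{sign}(s)\,[\tfrac{1}{\alpha}\log(e^{\alpha\xi} +
#'   e^{\alpha|s|} - 1) - \xi]}
#' pointwise. `xi = 0` gives the identity (the standard sparse code);
#' large `xi` approaches soft thresholding \eqn{\max(|s| - \xi, 0)}.
#' Evaluation is overflow-safe via a log-sum-exp rearrangement around
#' \eqn{M = \max(\xi, |s|)}, and the exact identities `z = s` at `xi = 0`
#' and `z = 0` at `s = 0` hold bitwise.
#'
#' @param s Code vector, or matrix of codes with neurons in columns.
#' @param xi Nonnegative threshold(s): scalar, length-`N` vector (recycled
#'   across rows of a matrix `s`), or a matrix matching `s`.
#' @param alpha Smoothness constant (default 10).
#' @return Responses with the shape of `s`.
#' @export
shrink <- function(s, xi, alpha = 10) {
  if (any(xi < 0)) abort("thresholds `xi` must be nonnegative")
  if (alpha <= 0) abort("`alpha` must be positive")
  if (is.matrix(s)) {
    if (is.matrix(xi)) {
      if (!all(dim(xi) == dim(s))) abort("`xi` matrix shape mismatch")
      Xi <- xi
    } else if (length(xi) == 1) {
      Xi <- matrix(xi, nrow(s), ncol(s))
    } else {
      if (length(xi) != ncol(s)) abort("length of `xi` must match neurons")
      Xi <- matrix(xi, nrow(s), ncol(s), byrow = TRUE)
    }
    out <- shrink_cpp(s, Xi, alpha)
    dimnames(out) <- dimnames(s)
    out
  } else {
    if (length(xi) == 1) xi <- rep(xi, length(s))
    if (length(xi) != length(s)) abort("lengths of `s` and `xi` differ")
    as.numeric(shrink_cpp(matrix(s, 1), matrix(xi, 1), alpha))
  }
}

#' Effective gain of the shrinkage nonlinearity
#'
#' Slope of the least-squares line fit (unconstrained intercept) of the
#' shrinkage output against its input over a uniform grid on `s_range`.
#' The gain is 1 at `xi = 0` and decreases strictly with `xi`, which is the
#' sense in which raising the threshold lowers the neuron's response gain.
#'
#' @param xi Threshold (scalar).
#' @param alpha Smoothness constant.
#' @param s_range Interval of inputs, must span positive values.
#' @param n_grid Grid points for the fit.
#' @export
effective_gain <- function(xi, alpha = 10, s_range = c(0, 3), n_grid = 100) {
  if (length(s_range) != 2 || diff(s_range) <= 0) {
    abort("`s_range` must be a nonempty increasing interval")
  }
  if (max(s_range) <= 0) abort("`s_range` must span positive values")
  s <- seq(s_range[1], s_range[2], length.out = n_grid)
  z <- shrink(s, rep(xi, n_grid), alpha)
  unname(coef(stats::lm(z ~ s))[2])
}

#' Expected activity under a threshold setting
#'
#' Monte-Carlo estimate of the expected response magnitude
#' \eqn{\langle |z_n| \rangle} per neuron: the quantity used to visualize a
#' threshold vector as the experimentally observable expected activity map.
#' Supply either a precomputed code matrix (rows = stimulus samples) or a
#' sampler function returning one.
#'
#' @param codes `n x N` matrix of sparse codes, or a function
#'   `function(n_samples)` generating one.
#' @param xi Threshold vector (length `N`).
#' @param alpha Smoothness constant.
#' @param n_samples Number of samples when `codes` is a sampler.
#' @return Length-`N` vector of expected response magnitudes.
#' @export
expected_activity <- function(codes, xi, alpha = 10, n_samples = NULL) {
  if (is.function(codes)) {
    n_samples <- check_count(n_samples %||% 100, "n_samples")
    codes <- codes(n_samples)
  }
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1)
  colMeans(abs(shrink(codes, xi, alpha)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
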