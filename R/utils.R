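# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  force(seed)
  withr::with_seed(seed, code)
}

# Standardize a vector (or each row of a matrix) to zero mean, unit variance.
# Uses the population variance so that var(pixels) == 1 exactly.
standardize <- function(x) {
  if (is.matrix(x)) {
    ctr <- x - rowMeans(x)
    s <- sqrt(rowMeans(ctr^2))
    if (any(s == 0)) {
      abort("cannot standardize a constant patch (zero variance)")
    }
    ctr / s
  } else {
    ctr <- x - mean(x)
    s <- sqrt(mean(ctr^2))
    if (s == 0) abort("cannot standardize a constant patch (zero variance)")
    ctr / s
  }
}

# Coerce a single patch (vector or W x W matrix) to a pixel vector, checking
# its length against an expected width when given.
as_patch_vector <- function(x, W = NULL) {
  if (is.matrix(x)) x <- as.vector(t(x))
  if (!is.null(W) && length(x) != W * W) {
    abort(sprintf("patch has %d pixels, expected %d (W = %d)",
                  length(x), W * W, W))
  }
  x
}

# Rows-as-patches matrix from a vector, matrix, or list of patches.
as_patch_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, lapply(x, as_patch_vector))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  x
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

# Pearson correlation that returns 0 (with a "flagged" attribute on the
# caller side) instead of NA for zero-variance inputs.
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}
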