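test_that("decoding is the linear feature superposition around the mean", {
  dict <- get_ortho_dict()
  mu <- dict$pca$mean
  expect_equal(decode(rep(0, 12), dict), mu, tolerance = 1e-12)
  e3 <- rep(0, 12); e3[3] <- 1
  atom3 <- as.numeric(dict$pca$rotation[, 3])
  expect_equal(decode(e3, dict), mu + atom3, tolerance = 1e-12)
  # linearity up to the mean offset
  s1 <- runif(12); s2 <- runif(12)
  lhs <- decode(2 * s1 + 3 * s2, dict)
  rhs <- 2 * decode(s1, dict) + 3 * decode(s2, dict) - 4 * mu
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_error(decode(rep(0, 5), dict), "length")
})

test_that("energy matches term-by-term hand computation", {
  # 3-neuron toy dictionary in a 2-d reduced space
  pca <- structure(list(mean = rep(0, 4),
                        rotation = cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
                        d = 2L, W = 2L, var_explained = c(0.6, 0.4)),
                   class = "ac_pca")
  Phi <- rbind(c(1, 0), c(0, 1), c(1, 1) / sqrt(2))
  dict <- adaptcode:::new_dictionary(Phi, pca, sc_config(lambda = 0.3,
                                                         sigma2 = 0.5))
  y <- c(0.7, -0.2)
  s <- c(0.5, -0.1, 0.2)
  xhat <- as.numeric(t(Phi) %*% s)
  hand <- sum((xhat - y)^2) / (2 * 0.5) + 0.3 * sum(abs(s))
  expect_equal(energy(y, s, dict, reduced = TRUE), hand, tolerance = 1e-12)
  expect_equal(energy(rep(0, 2), rep(0, 3), dict, reduced = TRUE), 0)
  expect_equal(energy(y, rep(0, 3), dict, reduced = TRUE),
               sum(y^2) / (2 * 0.5), tolerance = 1e-12)
})

test_that("encoding solves the l1 problem (orthonormal closed form)", {
  dict <- get_ortho_dict()
  y <- withr::with_seed(4, rnorm(12))
  # lambda -> 0: least squares (here the projection itself)
  s0 <- encode(y, dict, sc_config(lambda = 1e-10, sigma2 = 0.5,
                                  max_iter = 2000), reduced = TRUE)
  expect_equal(as.numeric(s0), y, tolerance = 1e-5)
  # lambda > 0: soft threshold at lambda * sigma^2
  cfg <- sc_config(lambda = 0.4, sigma2 = 0.5, tol = 1e-12, max_iter = 2000)
  s <- encode(y, dict, cfg, reduced = TRUE)
  oracle <- sign(y) * pmax(abs(y) - 0.4 * 0.5, 0)
  expect_equal(as.numeric(s), oracle, tolerance = 1e-6)
  # huge penalty silences the code
  s_big <- encode(y, dict, sc_config(lambda = 1e4), reduced = TRUE)
  expect_true(all(abs(s_big) < 1e-10))
  # encoding never exceeds the energy of the zero code
  dict2 <- get_tiny_dict()
  x <- generate_patches(3, 8, seed = 21)
  cfg2 <- sc_config(lambda = 0.1)
  S <- encode(x, dict2, cfg2)
  expect_true(all(energy(x, S, dict2, cfg2) <=
                    energy(x, matrix(0, 3, dict2$N), dict2, cfg2) + 1e-9))
})

test_that("encoder matches a long proximal-gradient oracle on small cases", {
  # independent oracle: plain ISTA run to tight tolerance
  ista <- function(y, Phi, lambda, sigma2, iters = 20000) {
    L <- max(eigen(Phi %*% t(Phi), symmetric = TRUE)$values) / sigma2
    s <- rep(0, nrow(Phi))
    for (i in seq_len(iters)) {
      g <- as.numeric(Phi %*% (t(Phi) %*% s - y)) / sigma2
      s <- sign(s - g / L) * pmax(abs(s - g / L) - lambda / L, 0)
    }
    s
  }
  for (seed in 1:4) {
    withr::with_seed(seed, {
      N <- sample(4:12, 1); d <- sample(4:12, 1)
      Phi <- matrix(rnorm(N * d), N, d)
      Phi <- Phi / sqrt(rowSums(Phi^2))
      y <- rnorm(d)
    })
    lambda <- 0.2; sigma2 <- 0.5
    s_or <- ista(y, Phi, lambda, sigma2)
    s_f <- adaptcode:::fista_encode(matrix(y, 1), Phi, lambda, sigma2,
                                    tol = 1e-12, max_iter = 5000)
    en <- function(s) sum((y - as.numeric(t(Phi) %*% s))^2) / (2 * sigma2) +
      lambda * sum(abs(s))
    expect_lt(abs(en(as.numeric(s_f)) - en(s_or)), 1e-6)
  }
})

test_that("dictionary learning keeps unit norms, reduces energy, is seeded", {
  corpus <- generate_patches(500, 8, seed = 31, model = "leaves")
  d1 <- suppressWarnings(
    learn_dictionary(corpus, N = 20, cfg = sc_config(lambda = 1),
                     epochs = 3, batch_size = 50, d = 20, seed = 11))
  expect_lt(max(abs(rowSums(d1$features^2) - 1)), 1e-8)
  tr <- attr(d1, "energy_trace")
  expect_lte(tr[3], tr[1] + 1e-6)
  d2 <- suppressWarnings(
    learn_dictionary(corpus, N = 20, cfg = sc_config(lambda = 1),
                     epochs = 3, batch_size = 50, d = 20, seed = 11))
  expect_identical(d1$features, d2$features)
  expect_error(learn_dictionary(matrix(1, 50, 16), N = 8),
               "zero variance|standardize|degenerate")
})
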