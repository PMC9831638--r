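test_that("generated patches are standardized and seed-deterministic", {
  X <- generate_patches(10, W = 16, seed = 1)
  expect_equal(dim(X), c(10, 256))
  expect_lt(max(abs(rowMeans(X))), 1e-9)
  expect_lt(max(abs(rowMeans(X^2) - 1)), 1e-9)
  expect_true(all(is.finite(X)))
  expect_identical(X, generate_patches(10, W = 16, seed = 1))
  expect_false(identical(X, generate_patches(10, W = 16, seed = 2)))
  L <- generate_patches(6, W = 16, seed = 4, model = "leaves")
  expect_lt(max(abs(rowMeans(L))), 1e-9)
  expect_identical(L, generate_patches(6, W = 16, seed = 4,
                                       model = "leaves"))
  expect_error(generate_patches(0, 16), "integer")
  expect_error(generate_patches(5, 2), "integer")
})

test_that("patch ensemble has the requested power-law spectrum", {
  # independent oracle: radially averaged periodogram, log-log slope fit
  W <- 32
  X <- generate_patches(500, W = W, spectral_exponent = 2, seed = 7)
  P <- matrix(0, W, W)
  for (i in seq_len(nrow(X))) {
    m <- matrix(X[i, ], W, W, byrow = TRUE)
    P <- P + Mod(stats::fft(m))^2
  }
  k <- ((0:(W - 1) + W %/% 2) %% W) - W %/% 2
  rad <- round(sqrt(outer(k^2, k^2, "+")))
  pw <- tapply(as.numeric(P), as.numeric(rad), mean)
  f <- as.numeric(names(pw))
  ok <- f >= 1 & f <= W / 2
  slope <- unname(coef(lm(log(pw[ok]) ~ log(f[ok])))[2])
  expect_lt(abs(slope - (-2)), 0.3)
})

test_that("movies drift on a torus with correlated frames", {
  M0 <- generate_movie(5, W = 16, drift = 0, seed = 3)
  expect_true(all(M0[1, ] == M0[5, ]))
  M1 <- generate_movie(20, W = 16, drift = 1, seed = 3)
  cors <- vapply(1:19, function(t) cor(M1[t, ], M1[t + 1, ]), numeric(1))
  expect_gt(min(cors), 0.5)
  # torus periodicity: after W / drift frames the first frame recurs
  M <- generate_movie(17, W = 16, drift = 1, seed = 11)
  expect_equal(M[1, ], M[17, ], tolerance = 1e-12)
  expect_error(generate_movie(5, W = 16, drift = 20), "drift")
})

test_that("templates have the prescribed cross and a reproducible object", {
  tpl <- make_templates(16, seed = 3)
  expect_equal(sum(tpl$cross != 0), 13)
  expect_equal(dim(tpl$cross), c(7, 7))
  expect_true(all(tpl$cross[tpl$cross != 0] == tpl$cross[4, 4]))
  expect_identical(tpl$object, make_templates(16, seed = 3)$object)
  expect_gt(var(as.numeric(tpl$object)), 0)
  expect_lt(abs(mean(tpl$object)), 1e-9)
  # object contrast scales the template's pixel variance
  t2 <- make_templates(16, seed = 3, object_contrast = 1)
  expect_equal(mean(t2$object^2), 1, tolerance = 1e-9)
})

test_that("object embedding is the stated linear mixture", {
  x <- generate_patches(1, 16, seed = 2)[1, ]
  tpl <- make_templates(16, seed = 3)
  expect_equal(embed_object(x, tpl$object, 0), x, ignore_attr = TRUE)
  expect_equal(embed_object(x, tpl$object, 1), as.numeric(tpl$object),
               ignore_attr = TRUE)
  expect_equal(embed_object(rep(0, 256), tpl$object, 0.2),
               0.2 * as.numeric(tpl$object), ignore_attr = TRUE)
  expect_error(embed_object(x[1:10], tpl$object, 0.2), "mismatch")
  expect_error(embed_object(x, tpl$object, 1.5), "gamma")
})

test_that("target superposition rounds, clips and overwrites arm pixels", {
  tpl <- make_templates(32, seed = 1)
  z <- rep(0, 32 * 32)
  out <- superimpose_target(z, tpl$cross, c(16.4, 16.6))
  img <- matrix(out, 32, 32, byrow = TRUE)
  expect_equal(sum(img != 0), 13)
  expect_true(all(img[16, 14:20] != 0))   # row arm at rounded center (16, 17)
  expect_true(all(img[13:19, 17] != 0))
  clipped <- superimpose_target(z, tpl$cross, c(-5, 40))
  imgc <- matrix(clipped, 32, 32, byrow = TRUE)
  expect_true(imgc[1, 32] != 0)           # center clipped to (1, 32)
  expect_true(all(which(imgc != 0, arr.ind = TRUE)[, 1] <= 4))
  # center position on zero frame: exactly 13 white pixels at cross value
  ctr <- superimpose_target(z, tpl$cross, c(16, 16))
  expect_equal(sum(ctr == tpl$cross[4, 4]), 13)
})

test_that("gratings follow the orientation and phase conventions", {
  g0 <- matrix(make_grating(0, 3, 0, 16), 16, 16, byrow = TRUE)
  expect_lt(max(apply(g0, 1, var)), 1e-18)   # rows constant
  expect_equal(make_grating(35, 3, 0.4, 16),
               make_grating(215, 3, 0.4, 16), tolerance = 1e-12)
  expect_equal(make_grating(50, 4, 0.3 + pi, 16),
               -make_grating(50, 4, 0.3, 16), tolerance = 1e-9)
  expect_error(make_grating(10, 0, 0, 16), "frequency")
  g <- make_grating(77, 5, 1, 16)
  expect_lt(abs(mean(g)), 1e-12)
  expect_equal(mean(g^2), 1, tolerance = 1e-9)
})

test_that("PCA preprocessing is orthonormal and idempotent in its span", {
  X <- generate_patches(120, 8, seed = 6)
  p <- preprocess_corpus(X, 20)
  G <- t(p$rotation) %*% p$rotation
  expect_lt(max(abs(G - diag(20))), 1e-8)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
  # projecting then back-projecting reduced coordinates is exact
  Y <- adaptcode:::pca_project(p, X[1:5, ])
  Xb <- adaptcode:::pca_backproject(p, Y)
  Y2 <- adaptcode:::pca_project(p, Xb)
  expect_equal(Y, Y2, tolerance = 1e-10)
  # complete basis reconstructs exactly
  pf <- preprocess_corpus(X, 64)
  Xr <- adaptcode:::pca_backproject(pf, adaptcode:::pca_project(pf, X[1:5, ]))
  expect_lt(max(abs(Xr - X[1:5, ])), 1e-8)
  expect_error(preprocess_corpus(X, 65), "exceeds")
})
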