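test_that("the inference-error term obeys its exact identities", {
  tb <- toy_binary_problem()
  N <- ncol(tb$smp$S)
  expect_identical(symmetrized_kl_posteriors(rep(0, N), tb$smp, tb$ctx), 0)
  # Bernoulli symmetrized KL: hand formula and symmetry
  kl <- adaptcode:::sym_kl_bernoulli
  expect_equal(kl(0.8, 0.6), (0.8 - 0.6) * log(0.8 * 0.4 / (0.6 * 0.2)),
               tolerance = 1e-12)
  expect_equal(kl(0.8, 0.6), kl(0.6, 0.8))
  expect_equal(kl(0.5, 0.5), 0)
  expect_false(is.na(kl(1, 0)))     # extreme posteriors never NaN
  expect_false(is.na(kl(0, 0)))
})

test_that("the total cost decomposes into inference error plus activity", {
  tb <- toy_binary_problem()
  N <- ncol(tb$smp$S)
  # xi = 0: pure activity
  expect_equal(total_cost(rep(0, N), tb$smp, tb$ctx, psi = 4),
               4 * sum(colMeans(abs(tb$smp$S))), tolerance = 1e-12)
  # psi = 0: inference error only, minimized (0) at xi = 0
  expect_equal(total_cost(rep(0, N), tb$smp, tb$ctx, psi = 0), 0)
  xi <- c(0.5, 1, 0.2)
  expect_gte(total_cost(xi, tb$smp, tb$ctx, psi = 0), 0)
  # spreadsheet-style hand computation on a 2-sample, 2-neuron toy
  models <- fit_class_models(c(0.3, 2.1, -0.4, -2.2), rep(c("P", "A"), each = 2))
  ctx <- structure(list(task = "detection", w = c(1, 2), c0 = 0,
                        models = models, positive = "P", negative = "A"),
                   class = "ac_context")
  smp <- structure(list(S = rbind(c(2, -1), c(0.5, 0.3)),
                        zeta = c(0.05, -0.02), prior = 0.6, n = 2,
                        task = "detection"), class = "ac_cost_samples")
  xi2 <- c(0.4, 0.1)
  Z <- shrink(smp$S, xi2)
  m1 <- as.numeric(Z %*% c(1, 2)) + smp$zeta
  m0 <- as.numeric(smp$S %*% c(1, 2)) + smp$zeta
  post <- function(m) {
    lp <- dnorm(m, models$mu[models$class == "P"],
                models$sigma[models$class == "P"], log = TRUE)
    la <- dnorm(m, models$mu[models$class == "A"],
                models$sigma[models$class == "A"], log = TRUE)
    plogis(qlogis(0.6) + lp - la)
  }
  p1 <- post(m1); p0 <- post(m0)
  hand_kl <- mean((p1 - p0) * (qlogis(p1) - qlogis(p0)))
  hand <- hand_kl + 4 * sum(colMeans(abs(Z)))
  expect_equal(total_cost(xi2, smp, ctx, psi = 4), hand, tolerance = 1e-10)
})

test_that("the R cost and the compiled optimizer cost agree", {
  fx <- get_fixture()
  ctx <- fx$detection
  smp <- suppressWarnings(draw_cost_samples(ctx, 0.5, n = 60, seed = 5))
  opt <- optimize_thresholds(smp, ctx, optim_config(psi = 4, n_mc = 60,
                                                    max_iter = 30), seed = 2)
  expect_equal(opt$cost, total_cost(opt$xi, smp, ctx, psi = 4),
               tolerance = 1e-10)
})

test_that("Rprop drives the cost down and to zero when activity is free", {
  fx <- get_fixture()
  ctx <- fx$detection
  smp <- suppressWarnings(draw_cost_samples(ctx, 0.5, n = 80, seed = 5))
  opt0 <- optimize_thresholds(smp, ctx, optim_config(psi = 0, n_mc = 80),
                              seed = 2)
  expect_lt(opt0$cost, 1e-4)        # known optimum at xi = 0
  expect_true(all(diff(opt0$trace) <= 1e-12))
  opt4 <- optimize_thresholds(smp, ctx, optim_config(psi = 4, n_mc = 80),
                              seed = 2)
  expect_true(all(diff(opt4$trace) <= 1e-12))
  expect_true(all(opt4$xi >= 0))
  # deterministic given seeds
  opt4b <- optimize_thresholds(smp, ctx, optim_config(psi = 4, n_mc = 80),
                               seed = 2)
  expect_identical(opt4$xi, opt4b$xi)
})

test_that("numerical cost gradients are stable across probe scales", {
  tb <- toy_binary_problem(n = 120)
  a <- withr::with_seed(21, rnorm(3, 0, 0.4))
  grad_at <- function(h) {
    vapply(1:3, function(k) {
      ap <- a; am <- a
      ap[k] <- a[k] + h; am[k] <- a[k] - h
      (total_cost(ap^2, tb$smp, tb$ctx, psi = 2) -
         total_cost(am^2, tb$smp, tb$ctx, psi = 2)) / (2 * h)
    }, numeric(1))
  }
  g1 <- grad_at(1e-3)
  g2 <- grad_at(1e-4)
  expect_lt(max(abs(g1 - g2)) / max(abs(g2)), 1e-3)
})

test_that("threshold selection matches a brute-force scan", {
  tab <- structure(list(
    xi = matrix(seq_len(32 * 4), 32, 4), grid = seq_len(32) / 32,
    task = "detection", psi = 4, valid = rep(TRUE, 32)),
    class = "ac_threshold_table")
  expect_equal(attr(select_thresholds(tab, 3 / 32), "index"), 3L)
  # midway between two grid points: lower index wins
  expect_equal(attr(select_thresholds(tab, 3.5 / 32), "index"), 3L)
  for (p in withr::with_seed(3, runif(25))) {
    brute <- which.min((tab$grid - p)^2)
    expect_equal(attr(select_thresholds(tab, p), "index"), brute)
  }
  ptab <- structure(list(
    xi = matrix(0, 9, 4),
    grid = as.matrix(expand.grid(row = c(1, 8, 16), col = c(1, 8, 16))),
    task = "localization", psi = 4, valid = rep(TRUE, 9)),
    class = "ac_threshold_table")
  for (i in 1:9) {
    expect_equal(attr(select_thresholds(ptab, ptab$grid[i, ]), "index"), i)
  }
})

test_that("detection tables mix training classes by the grid probability", {
  fx <- get_fixture()
  smp1 <- suppressWarnings(draw_cost_samples(fx$detection, 1, n = 40,
                                             seed = 2))
  # p = 1: every sample carries the object (large template projections)
  m <- fx$detection$c0 + as.numeric(smp1$S %*% fx$detection$w)
  pp <- adaptcode:::class_par(fx$detection$models, "P")
  expect_true(all(m > pp["mu"] - 4 * pp["sigma"]))
  smp0 <- suppressWarnings(draw_cost_samples(fx$detection, 0, n = 40,
                                             seed = 2))
  m0 <- fx$detection$c0 + as.numeric(smp0$S %*% fx$detection$w)
  pa <- adaptcode:::class_par(fx$detection$models, "A")
  expect_lt(mean(m0), pa["mu"] + 4 * pa["sigma"])
})

test_that("table entries differ across beliefs and favor the spotlight", {
  tab <- get_table("detection")
  expect_true(all(tab$valid))
  expect_gt(max(abs(tab$xi[1, ] - tab$xi[8, ])), 0)
  ltab <- get_table("localization")
  fx <- get_fixture()
  ctr <- adaptcode:::atom_centroids(fx$dict)
  # center entry: atoms near the believed position get lower thresholds
  i_ctr <- which.min((ltab$grid[, 1] - 8.5)^2 + (ltab$grid[, 2] - 8.5)^2)
  dist <- sqrt((ctr[, 1] - 8.5)^2 + (ctr[, 2] - 8.5)^2)
  near <- dist <= quantile(dist, 1 / 3)
  far <- dist >= quantile(dist, 2 / 3)
  expect_lt(mean(ltab$xi[i_ctr, near]), mean(ltab$xi[i_ctr, far]))
})

test_that("ROI compression trades reconstruction for activity", {
  fx <- get_fixture()
  x <- generate_patches(1, 16, seed = 77, model = "leaves")[1, ]
  roi <- rep(FALSE, 256)
  roi[as.vector(outer((4:9 - 1) * 16, 4:9, "+"))] <- TRUE   # 6x6 block
  sweep <- suppressWarnings(
    roi_compress(x, roi, dict = fx$dict, cfg = sc_config(lambda = 0.1),
                 ocfg = optim_config(max_iter = 300), seed = 3))
  # psi = 0 reproduces the full-code reconstruction
  s <- suppressWarnings(encode(x, fx$dict, sc_config(lambda = 0.1)))
  full_rec <- decode(s, fx$dict)
  expect_lt(max(abs(sweep$recon[[1]] - full_rec)), 1e-6)
  # activity is non-increasing along the sweep
  expect_true(all(diff(sweep$activity) <= 1e-8))
  # the ROI is reconstructed better than the rest at every psi > 0
  expect_true(all(sweep$snr_roi[-1] >= sweep$snr_out[-1]))
  expect_error(roi_compress(x, rep(FALSE, 256), dict = fx$dict), "empty")
})
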