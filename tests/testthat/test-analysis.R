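test_that("SNR and kurtosis follow their definitions", {
  x <- c(1, 2, 3, -1)
  expect_equal(snr_db(x, x), Inf)
  expect_equal(snr_db(x, rep(0, 4)), 0)
  expect_equal(snr_db(rep(0, 4), x), -Inf)
  # residual power a tenth of the signal: 10 dB
  xb <- rep(1, 10)
  expect_equal(snr_db(xb, xb - sqrt(0.1)), 10, tolerance = 1e-12)
  expect_equal(snr_db(x, rep(0, 4), const = 20), 0)
  expect_equal(snr_db(x, c(1, 2, 0, -1), mask = 1:2), Inf)
  g <- withr::with_seed(2, rnorm(1e5))
  expect_lt(abs(kurtosis(g) - 3), 0.2)
  expect_true(is.na(kurtosis(rep(1, 5))))
})

test_that("response statistics flag activity against each neuron's peak", {
  Z <- rbind(c(1, 0, 0.004), c(0.5, 0, 0.5), c(0.009, 0, 0.2))
  st <- response_statistics(Z)
  expect_equal(st$active_count, c(1, 2, 1))
  expect_true(all(!st$active[, 2]))    # constant-zero neuron never active
  expect_equal(st$mean_abs, colMeans(abs(Z)))
})

test_that("binary entropy is exact at its landmarks", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))
  p <- seq(0.01, 0.99, by = 0.01)
  h <- binary_entropy(p)
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(which.max(h), which(p == 0.5))
})

test_that("uncertainty binning aggregates the trace by prior entropy", {
  fx <- get_fixture()
  tr <- get_trace("detection", "adaptive")
  up <- uncertainty_profile(tr, fx$dict)
  expect_true(all(diff(up$uncertainty) > 0))
  expect_equal(sum(up$n), nrow(tr$steps))
  expect_true(all(up$mean_activity >= 0))
  up3 <- uncertainty_profile(tr, fx$dict, bins = "thirds")
  expect_lte(nrow(up3), 3)
  # cumulative variance curves are monotone and end at 1
  cv <- up$cumvar[[which.max(up$n)]]
  expect_true(all(diff(cv) >= -1e-12))
  expect_equal(cv[length(cv)], 1, tolerance = 1e-9)
})

test_that("task-modulated correlation matrices behave as contracts say", {
  fx <- get_fixture()
  tr_a <- get_trace("detection", "adaptive")
  tr_f <- get_trace("detection", "full")
  same <- task_correlations(tr_f$S, tr_f$S, n_select = 10)
  expect_equal(same$corr_full, same$corr_adaptive)
  tc <- task_correlations(tr_f$S, tr_a$Z, n_select = 10)
  expect_equal(diag(tc$corr_full), rep(1, 10))
  expect_gt(norm(tc$corr_full - tc$corr_adaptive, "F"), 0)
})

test_that("belief-driven noise correlations emerge only under a varying belief", {
  fx <- get_fixture()
  tab <- get_table("detection")
  stim <- generate_patches(1, 16, seed = 321, model = "leaves")[1, ]
  nc <- suppressWarnings(noise_correlation_experiment(
    stim, fx$detection, tab, n_rep = 300, seed = 5))
  # full-code baseline: essentially uncorrelated
  expect_lt(mean_abs_offdiag(nc$corr_full), 0.05)
  expect_equal(max(nc$sv_adaptive), 1)
  expect_equal(max(nc$sv_full), 1)
  # a constant belief driver leaves only the iid noise
  ctab <- tab
  ctab$xi <- ctab$xi[rep(4, nrow(ctab$xi)), ]
  ncc <- suppressWarnings(noise_correlation_experiment(
    stim, fx$detection, ctab, n_rep = 300, seed = 5))
  expect_lt(mean_abs_offdiag(ncc$corr_adaptive), 0.05)
})

test_that("tuning curves respond to the attended threshold condition", {
  fx <- get_fixture()
  # identical threshold conditions give identical curves
  tc0 <- suppressWarnings(tuning_curve_analysis(
    fx$dict, cfg = sc_config(lambda = 0.1), n_orient = 8,
    frequencies = c(3, 5), phases = c(0, pi / 2),
    xi_attended = rep(0, fx$N), xi_unattended = rep(0, fx$N)))
  at <- tc0[tc0$condition == "attended", ]
  un <- tc0[tc0$condition == "unattended", ]
  expect_equal(at$peak, un$peak)
  expect_equal(at$preferred, un$preferred)
  expect_true(all(vapply(tc0$curve, function(cv) all(cv >= 0), logical(1))))
})

test_that("gain dynamics summaries are normalized and baseline-controlled", {
  fx <- get_fixture()
  tr <- get_trace("localization", "adaptive")
  gd <- gain_dynamics_analysis(tr, fx$dict, seed = 2)
  # per-neuron autocorrelations are 1 at lag zero
  expect_equal(gd$mean_acf[1], 1, tolerance = 1e-9)
  expect_true(all(gd$decay$decay_time >= 0))
  expect_true(nrow(gd$binned) >= 3)
  # threshold correlations rise with tuning similarity; shuffling flattens
  expect_gt(cor(gd$binned$tuning, gd$binned$gain, method = "spearman"), 0)
  fit_raw <- coef(lm(gain ~ tuning, data = gd$binned))[2]
  fit_sh <- coef(lm(gain_shuffled ~ tuning, data = gd$binned))[2]
  expect_lt(abs(fit_sh), abs(fit_raw))
})

test_that("the grating-mixture fit favors the dominant component", {
  fx <- get_fixture()
  tr <- get_trace("orientation", "adaptive")
  gm <- suppressWarnings(grating_mixture_analysis(
    fx$dict, tr, n_trials = 25, n_rep = 60, seed = 4))
  expect_gt(mean(gm$trials$alpha1), mean(gm$trials$alpha2))
  expect_true(all(is.finite(gm$noise_corr$corr)))
  # shuffled gains flatten the dependence on preferred-orientation difference
  expect_lte(diff(range(gm$noise_corr$corr_shuffled)),
             diff(range(gm$noise_corr$corr)) + 0.05)
})

test_that("code dimensionality grows with perceptual uncertainty", {
  # components needed for 90% of response variance, non-decreasing from the
  # most certain to the most uncertain bin, on detection traces across five
  # seeds
  fx <- get_fixture()
  ok_all <- vapply(55:59, function(sd_) {
    tr <- get_trace("detection", "adaptive", seed = sd_)
    up <- uncertainty_profile(tr, fx$dict)
    usable <- which(!is.na(up$n90) & up$n > 20)
    lo <- usable[which.min(up$uncertainty[usable])]
    hi <- usable[which.max(up$uncertainty[usable])]
    up$n90[hi] >= up$n90[lo]
  }, logical(1))
  expect_true(all(ok_all))
})
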