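test_that("detection measurement projects the decoded image on the template", {
  dict <- get_tiny_dict()
  tpl <- make_templates(8, seed = 2)
  obj <- as.numeric(tpl$object)
  # z = 0, no noise: the PCA mean's projection
  m0 <- measure_detection(rep(0, dict$N), dict, obj, measurement_noise(0))
  expect_equal(m0, sum(dict$pca$mean * obj), tolerance = 1e-10)
  z <- withr::with_seed(5, rnorm(dict$N))
  m1 <- measure_detection(z, dict, obj, measurement_noise(0))
  m2 <- measure_detection(z, dict, obj, measurement_noise(0))
  expect_identical(m1, m2)
  expect_equal(m1, sum(decode(z, dict) * obj), tolerance = 1e-8)
  # noise variance sampling check (task reference value 0.01)
  draws <- withr::with_seed(6, vapply(1:1000, function(i) {
    measure_detection(z, dict, obj, measurement_noise(0.01))
  }, numeric(1)))
  expect_lt(abs(var(draws) - 0.01) / 0.01, 0.2)
})

test_that("class models recover means and floor degenerate spreads", {
  m <- fit_class_models(c(0, 2, 1, 1, 1), c("a", "a", "b", "b", "b"))
  expect_equal(m$mu[m$class == "a"], 1)
  expect_equal(m$sigma[m$class == "a"], sqrt(2))
  expect_true(m$floored[m$class == "b"])
  expect_equal(m$sigma[m$class == "b"], 1e-6)
  big <- withr::with_seed(7, c(rnorm(1e4, 0, 1), rnorm(1e4, 3, 1)))
  fit <- fit_class_models(big, rep(c("lo", "hi"), each = 1e4))
  expect_lt(abs(fit$mu[fit$class == "lo"] - 0), 0.05)
  expect_lt(abs(fit$mu[fit$class == "hi"] - 3), 0.05)
  expect_error(fit_class_models(1:3, c("a", "a", "b")), "2 samples")
})

test_that("binary belief update equals direct density-ratio arithmetic", {
  models <- fit_class_models(c(1, 1.2, 0.8, -1, -1.2, -0.8),
                             rep(c("P", "A"), each = 3))
  # independent oracle: unnormalized Bayes rule with dnorm densities
  oracle <- function(prior, m) {
    lp <- dnorm(m, models$mu[models$class == "P"],
                models$sigma[models$class == "P"])
    la <- dnorm(m, models$mu[models$class == "A"],
                models$sigma[models$class == "A"])
    lp * prior / (lp * prior + la * (1 - prior))
  }
  for (case in list(c(0.5, 1), c(0.2, -0.4), c(0.9, 0.1), c(0.35, 2.5))) {
    upd <- update_binary_belief(case[1], case[2], models, h = 0)
    expect_equal(upd$posterior, oracle(case[1], case[2]), tolerance = 1e-12)
    expect_equal(upd$predictive, upd$posterior)
  }
  # hazard propagation and its approximation
  upd <- update_binary_belief(0.5, 1, models, h = 0.25)
  expect_equal(upd$predictive, 0.75 * upd$posterior +
                 0.25 * (1 - upd$posterior), tolerance = 1e-12)
  expect_equal(update_binary_belief(0.3, 9, models, h = 0.5)$predictive, 0.5)
  appr <- update_binary_belief(0.5, 1, models, h = 0.25,
                               approx_predictive = TRUE)
  expect_equal(appr$predictive, appr$posterior)
  # uninformative likelihood: posterior = prior
  eq <- fit_class_models(c(0, 1, 0, 1), rep(c("P", "A"), each = 2))
  expect_equal(update_binary_belief(0.37, 0.4, eq)$posterior, 0.37,
               tolerance = 1e-12)
  # extreme measurements stay finite (log-space computation)
  expect_false(is.na(update_binary_belief(0.5, 1e6, models)$posterior))
})

test_that("iterated belief updates concentrate on the true state", {
  models <- fit_class_models(
    withr::with_seed(1, c(rnorm(500, 1, 1), rnorm(500, -1, 1))),
    rep(c("P", "A"), each = 500))
  p <- 0.5
  ms <- withr::with_seed(2, rnorm(50, 1, 1))   # true state P
  for (m in ms) p <- update_binary_belief(p, m, models, h = 0)$predictive
  expect_gt(p, 0.9)
})

test_that("localization measurement finds the correlation peak", {
  fx <- get_fixture()
  dict <- fx$dict
  cross <- fx$templates$cross
  # clean cross at a known position, decoded through the full code
  frame <- superimpose_target(rep(0, 256), cross, c(10, 12))
  s <- suppressWarnings(encode(frame, dict, sc_config(lambda = 0.01)))
  expect_equal(unname(measure_localization(s, dict, cross)), c(10, 12))
  # constant (zero) image: every map entry ties, lexicographic minimum wins
  s0 <- rep(0, dict$N)
  dict0 <- dict
  dict0$pca$mean <- rep(0, 256)
  expect_equal(unname(measure_localization(s0, dict0, cross)), c(1, 1))
  # weak 1/f background, full code: within 1 pixel in >= 95% of trials
  hits <- 0
  for (i in 1:40) {
    bg <- generate_patches(1, 16, seed = 100 + i)[1, ]
    pos <- withr::with_seed(200 + i, sample(4:13, 2, replace = TRUE))
    fr <- superimpose_target(bg, 3 * (cross != 0), pos)  # contrast-3 cross
    s <- suppressWarnings(encode(fr, dict, sc_config(lambda = 0.05)))
    est <- measure_localization(s, dict, cross)
    if (max(abs(est - pos)) <= 1) hits <- hits + 1
  }
  expect_gte(hits / 40, 0.95)
})

test_that("position update matches an independent Kalman step", {
  # hand arithmetic from the conjugate formula
  up <- update_position_belief(list(mu = c(10, 10), var = c(4, 4)),
                               c(14, 14), noise_var = 4, walk_var = 1.44)
  expect_equal(up$mu, c(12, 12))
  expect_equal(up$var, c(2, 2))
  expect_equal(up$pred_var, c(3.44, 3.44))
  # limits
  expect_equal(update_position_belief(list(mu = 5, var = 2), 9,
                                      noise_var = 1e12)$mu, 5,
               tolerance = 1e-9)
  exact <- update_position_belief(list(mu = 5, var = 2), 9, noise_var = 0)
  expect_equal(exact$mu, 9)
  expect_equal(exact$var, 0)
  # independent oracle: Kalman gain form, 1e4 random cases
  withr::with_seed(9, {
    mu <- rnorm(1e4); v <- runif(1e4, 0.01, 10)
    m <- rnorm(1e4, mu, 1); r <- runif(1e4, 0.001, 5)
  })
  K <- v / (v + r)
  mu_k <- mu + K * (m - mu)
  var_k <- (1 - K) * v
  got_mu <- got_var <- numeric(1e4)
  for (i in seq_len(1e4)) {
    one <- update_position_belief(list(mu = mu[i], var = v[i]), m[i],
                                  noise_var = r[i])
    got_mu[i] <- one$mu
    got_var[i] <- one$var
  }
  expect_lt(max(abs(got_mu - mu_k)), 1e-10)
  expect_lt(max(abs(got_var - var_k)), 1e-10)
})

test_that("orientation categories separate pure gratings", {
  dict <- get_fixture()$dict
  oris <- rep(c(0, 90), each = 40)
  G <- t(vapply(seq_along(oris), function(i) {
    make_grating(oris[i], 3 + (i %% 3), (i %% 5) * 0.7, 16)
  }, numeric(256)))
  S <- suppressWarnings(encode(G, dict, sc_config(lambda = 0.05)))
  cats <- learn_orientation_categories(S, dict, k = 9, seed = 4)
  cats2 <- learn_orientation_categories(S, dict, k = 9, seed = 4)
  expect_identical(cats$cluster, cats2$cluster)
  purity <- function(members, want_first_half) {
    if (length(members) == 0) return(0)
    mean(if (want_first_half) members <= 40 else members > 40)
  }
  expect_gte(purity(cats$H, TRUE), 0.9)
  expect_gte(purity(cats$V, FALSE), 0.9)
})

test_that("log-ratio features floor silent neurons to a constant", {
  S <- cbind(c(1, -2, 0.5), rep(0, 3))
  R <- adaptcode:::log_ratio_features(S)
  expect_true(all(is.finite(R)))
  expect_equal(var(R[, 2]), 0)
})

test_that("the discriminant matches closed-form LDA geometry", {
  withr::with_seed(12, {
    R1 <- matrix(rnorm(300 * 4), 300, 4) +
      matrix(c(3, 0, 0, 0), 300, 4, byrow = TRUE)
    R2 <- matrix(rnorm(300 * 4), 300, 4)
  })
  disc <- learn_discriminant(R1, R2)
  # isotropic clouds: direction parallel to the mean difference
  dmu <- colMeans(R1) - colMeans(R2)
  cosang <- sum(disc$d * dmu) / sqrt(sum(dmu^2))
  expect_gt(abs(cosang), 0.99)
  expect_gt(disc$accuracy, 0.9)
  # cross-check against MASS::lda scaling direction
  fit <- MASS::lda(rbind(R1, R2), grouping = rep(c(1, 2), each = 300))
  v <- fit$scaling[, 1] / sqrt(sum(fit$scaling[, 1]^2))
  expect_gt(abs(sum(disc$d * v)), 0.999)
  # scale equivariance of the direction
  d2 <- learn_discriminant(2 * R1, 2 * R2)
  expect_gt(abs(sum(disc$d * d2$d)), 0.999)
  # identical classes: chance accuracy
  same <- withr::with_seed(13, matrix(rnorm(400), 100, 4))
  d3 <- learn_discriminant(same, same + 1e-9)
  expect_lt(abs(d3$accuracy - 0.5), 0.1)
})

test_that("orientation measurement pools magnitudes onto the discriminant", {
  d <- c(0.5, -0.5, 0.2)
  expect_equal(measure_orientation(c(0, 0, 0), d, measurement_noise(0)), 0)
  z <- c(1, -2, 3)
  expect_equal(measure_orientation(z, d, measurement_noise(0)),
               measure_orientation(-z, d, measurement_noise(0)))
  expect_equal(measure_orientation(z, d, measurement_noise(0)),
               sum(abs(z) * d))
  draws <- withr::with_seed(3, vapply(1:10000, function(i) {
    measure_orientation(z, d, measurement_noise(1e-4))
  }, numeric(1)))
  expect_lt(abs(var(draws) - 1e-4) / 1e-4, 0.2)
})

test_that("belief updates stay normalized under long random streams", {
  models <- fit_class_models(c(1, 1.4, 0.6, -1, -1.3, -0.7),
                             rep(c("P", "A"), each = 3))
  withr::with_seed(77, {
    ms <- rnorm(20000, 0, 50)    # wildly out-of-model measurements
  })
  p <- 0.5
  worst_ok <- TRUE
  for (m in ms) {
    upd <- update_binary_belief(p, m, models, h = 0.01)
    if (!is.finite(upd$predictive) || upd$predictive < 0 ||
        upd$predictive > 1) {
      worst_ok <- FALSE
      break
    }
    p <- upd$predictive
  }
  expect_true(worst_ok)
})
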