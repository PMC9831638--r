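# Shared fixtures, built once per test run and cached. All sizes follow the
# scaled working profile (W = 16, N = d = 128, k = 8 belief bins, 3x3
# position grid, psi = 4).

.ac_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .ac_cache)) {
    assign(key, force(expr), envir = .ac_cache)
  }
  get(key, envir = .ac_cache)
}

get_fixture <- function() {
  cached("fixture", suppressWarnings(study_fixture(seed = 1)))
}

get_table <- function(task, psi = 4) {
  cached(sprintf("table_%s_%g", task, psi), {
    fx <- get_fixture()
    ctx <- fx[[task]]
    cfg <- optim_config(psi = psi, n_mc = 250)
    suppressWarnings(
      if (task == "localization") {
        build_threshold_table(ctx, g = 3, cfg = cfg, seed = 31)
      } else {
        build_threshold_table(ctx, k = 8, cfg = cfg, seed = 31)
      })
  })
}

get_trace <- function(task, mode, seed = 55, T = 1200) {
  cached(sprintf("trace_%s_%s_%d_%d", task, mode, seed, T), {
    fx <- get_fixture()
    suppressWarnings(
      run_closed_loop(fx[[task]], get_table(task), T = T, seed = seed,
                      mode = mode))
  })
}

# A small dictionary on a fast corpus for unit tests that need a real
# encoder but not the full study setting.
get_tiny_dict <- function() {
  cached("tiny_dict", {
    corpus <- generate_patches(400, 8, seed = 5, model = "leaves")
    suppressWarnings(
      learn_dictionary(corpus, N = 24, cfg = sc_config(lambda = 1),
                       epochs = 2, batch_size = 50, d = 24, seed = 3))
  })
}

# Dictionary with exactly orthonormal features (identity in the reduced
# space) for closed-form encoder checks.
get_ortho_dict <- function() {
  cached("ortho_dict", {
    corpus <- generate_patches(80, 6, seed = 9)
    pca <- preprocess_corpus(corpus, 12)
    adaptcode:::new_dictionary(diag(12), pca, sc_config(lambda = 0.1))
  })
}

# Hand-specified detection-flavoured context + samples with known class
# models, for arithmetic-level cost checks.
toy_binary_problem <- function(prior = 0.5, n = 40, N = 3, seed = 2) {
  models <- fit_class_models(c(-1, 1, -1.2, 0.8, -0.9, 1.1),
                             class = c("A", "P", "A", "P", "A", "P"))
  ctx <- structure(list(task = "detection", w = c(1, -0.5, 0.25), c0 = 0.1,
                        models = models, positive = "P", negative = "A",
                        sd_m = 0.1, noise_var = 0.01),
                   class = "ac_context")
  smp <- withr::with_seed(seed, {
    list(S = matrix(stats::rnorm(n * N), n, N),
         zeta = stats::rnorm(n, 0, 0.1), prior = prior, n = n,
         task = "detection")
  })
  list(ctx = ctx, smp = structure(smp, class = "ac_cost_samples"))
}
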