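#' Build the study world: corpus, dictionary, templates and task contexts
#'
#' One call that constructs the complete simulation setting at a chosen
#' profile: the naturalistic synthetic corpus (dead-leaves textures with an
#' object embedded in a fraction of patches, mirroring a world in which the
#' detection target genuinely occurs), the PCA map and learned dictionary
#' (Gabor-bank initialization plus object-derived seed features), the task
#' templates, and the three observer contexts. The `"scaled"` profile
#' (`W = 16`, `N = d = 128`) is the default working size; `"full"` selects
#' the full-size setting (`W = 32`, `N = d = 512`), which is substantially
#' slower.
#'
#' @param profile `"scaled"` or `"full"`.
#' @param seed Master seed; all internal seeds derive from it.
#' @param n_corpus Dictionary-learning corpus size.
#' @param epochs Dictionary-learning epochs.
#' @param present_frac Fraction of corpus patches containing the object.
#' @param n_train Class-model training samples per state.
#' @param sigma_walk Localization random-walk standard deviation.
#' @param tasks Character vector of contexts to build (subset of
#'   `"detection"`, `"orientation"`, `"localization"`).
#' @param n_orient_corpus Corpus size for orientation-category discovery.
#' @return List with `dict`, `templates`, `corpus`, and contexts
#'   `detection`, `orientation`, `localization` (those requested).
#' @export
study_fixture <- function(profile = c("scaled", "full"), seed = 1,
                          n_corpus = NULL, epochs = 4, present_frac = 0.25,
                          n_train = NULL, sigma_walk = 1.2,
                          tasks = c("detection", "orientation",
                                    "localization"),
                          n_orient_corpus = NULL) {
  profile <- match.arg(profile)
  W <- if (profile == "scaled") 16L else 32L
  N <- if (profile == "scaled") 128L else 512L
  if (is.null(n_corpus)) n_corpus <- if (profile == "scaled") 4000 else 50000
  if (is.null(n_train)) n_train <- if (profile == "scaled") 400 else 10000
  if (is.null(n_orient_corpus)) {
    n_orient_corpus <- if (profile == "scaled") 1500 else 10000
  }
  tpl <- make_templates(W, seed = seed + 2)
  corpus <- generate_patches(n_corpus, W, seed = seed + 3, model = "leaves")
  emb <- with_seed(seed + 4, sample(n_corpus, round(present_frac * n_corpus)))
  corpus[emb, ] <- standardize(
    embed_object(corpus[emb, , drop = FALSE], tpl$object, 0.2))
  # object-derived seed features: whole template and canopy-only upper part
  ov <- as.numeric(tpl$object)
  half <- ov
  half[(W * W %/% 2 + 1):(W * W)] <- 0
  dict <- learn_dictionary(corpus, N = N, cfg = sc_config(lambda = 1),
                           epochs = epochs, batch_size = 50, d = N,
                           seed = seed + 5, init = "bank",
                           seed_atoms = rbind(ov, half))
  out <- list(dict = dict, templates = tpl, corpus = corpus,
              profile = profile, W = W, N = N, seed = seed)
  if ("detection" %in% tasks) {
    out$detection <- detection_context(dict, tpl$object, n_train = n_train,
                                       seed = seed + 6)
  }
  if ("orientation" %in% tasks) {
    # strongly orientation-coherent textures: the category structure the
    # estimation task discriminates
    ocorpus <- generate_patches(n_orient_corpus, W, seed = seed + 7,
                                model = "leaves", coherence = 0.95)
    out$orientation <- orientation_context(dict, ocorpus, seed = seed + 8)
  }
  if ("localization" %in% tasks) {
    out$localization <- localization_context(dict, tpl$cross,
                                             sigma_walk = sigma_walk)
  }
  out
}
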