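---
title: "Adaptive sparse population coding with belief-driven gain modulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive sparse population coding with belief-driven gain modulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`adaptcode` implements a normative model of attention-like, top-down
modulation of a sensory population. A bank of `N` model V1 neurons encodes
image patches with a sparse code: a patch `x` (standardized to zero mean and
unit pixel variance, reduced by PCA to `d` dimensions) is represented by
coefficients `s` minimizing

    E(s) = sum_i (xhat_i - x_i)^2 / (2 sigma^2) + lambda * sum_n |s_n| ,

where `xhat = sum_n phi_n s_n` and the features `phi_n` are unit-norm and
learned from the corpus (FISTA for the coefficients, mini-batch gradient
steps with row renormalization for the features). Each activation is then
passed through a smooth shrinkage nonlinearity

    z_n = sign(s_n) [ (1/alpha) log( e^{alpha xi_n} + e^{alpha |s_n|} - 1 ) - xi_n ] ,

with `alpha = 10`. At `xi_n = 0` the neuron's response equals the sparse
coefficient; raising `xi_n` lowers the neuron's effective gain and silences
weak activations.

A downstream Bayesian observer performs one of three perceptual tasks from
the responses `z` — object detection (is a known object embedded in the
patch?), target localization (where is a white cross moving on a drifting
background?), or orientation estimation (is the scene predominantly
horizontal or vertical?). At each step the observer takes a scalar (or 2-d)
measurement of `z`, updates its belief about the latent task state, and sets
the next step's threshold vector to the entry of a precomputed table that
minimizes the cost

    C(xi) = < D_KL_sym[ p(theta | z(xi)) || p(theta | z(0)) ] + psi * sum_n |z_n(xi_n)| >

over the predictive stimulus distribution of its current belief: the
expected inference error caused by compressing the code, plus `psi` times
the expected population activity (`psi = 4` throughout). Thresholds are
optimized offline per belief-grid point by resilient backpropagation (Rprop)
on auxiliary variables `a` with `xi = a^2`, using numerically estimated
gradients over a fixed Monte-Carlo sample set (common random numbers).

## Task parameters

All parameters named by the tasks keep their reference values: shrinkage
`alpha = 10`; resource constraint `psi = 4`; hazard rate `h = 0.01`; object
mixing coefficient `gamma = 0.2`; sparse-coding `sigma^2 = 0.5` with
`lambda = 1` for learning, `0.05` for detection and orientation, `0.1` for
localization; measurement-noise variances `0.01` (detection), `1e-10`
(localization, effectively vanishing), `1e-4` (orientation); random-walk
standard deviation `1.2` (low-uncertainty condition) or `2.4` (high);
scripted environments of 500 cycles of 50 positive / 100 negative / 50
positive samples; belief grids of `k = 32` probabilities `k/K` or a 5x5
position grid at full size. The scaled working profile used by the test
suite and the examples is `W = 16`, `N = d = 128`, `k = 8` bins, a 3x3
position grid, and Monte-Carlo sample sizes of 250 per grid point; the
full-size profile (`W = 32`, `N = d = 512`) is available through
`study_fixture(profile = "full")` and the size arguments of the individual
functions.

## The synthetic stimulus world

No image corpus ships with the package; `generate_patches()` synthesizes
one. Two texture models are provided. The `"spectral"` model is a Gaussian
random field with isotropic power spectrum `f^-gamma` (default exponent 2).
The `"leaves"` model is a dead-leaves texture: opaque elliptical elements
with scale-invariant sizes (`r^-3` density), random gray levels, partial
per-patch orientation coherence, painted back-to-front. Both have
approximately `1/f^2` power spectra; the leaves model in addition has the
sparse, edge-and-surface structure of natural movie frames.

The distinction matters. Sparse coding on Gaussian fields has no sparse
optimum: codes stay dense (every neuron active on every patch) and learned
features remain global. Under the cost `C(xi)` a dense code makes *keeping*
any neuron expensive, and the optimizer then prefers total suppression at
every belief — the closed loop goes blind and none of the belief-dependent
phenomenology exists. All study conditions therefore use the leaves model;
the spectral model remains available for spectrum-level experiments.

Three further stimulus-design choices define the study conditions, made
once on fidelity grounds and documented here:

* **The object is part of the world.** The dictionary-learning corpus
  contains the detection object embedded (at `gamma = 0.2`) in 25% of
  patches, and two object-derived patterns seed the feature initialization.
  A natural corpus from the object's habitat contains the object; a
  fully-converged learner would allocate features to any such recurring
  structure. Without object-tuned features the detector channel can only be
  kept at the price of generic background activity and the cost optimum
  collapses to total suppression at every belief.
* **Templates are contour-like and strongly discriminable.** The object
  template is a compact procedural tree silhouette band-passed to its
  contour band (`[0.2, 0.4] * W` cycles) and confined to its support, with
  a root-mean-square contrast of 12 on the standardized background scale;
  object-present frames are re-standardized to unit variance like every
  other stimulus. The localization cross uses arm value 5. Both contrasts
  are free parameters of the synthetic world (no reference values exist);
  the defaults are calibrated so that the measurement distributions of the
  two classes are clearly separated, as the tasks' design depicts, and the
  cross dominates the correlation map even when clipped at image borders.
  At much lower contrasts the tasks degenerate at this patch size: the
  inference-error term never outweighs `psi` times the cost of keeping any
  neurons, and again everything is suppressed.
* **Orientation categories come from coherent textures.** The
  orientation-estimation corpus uses orientation coherence 0.95, giving
  k-means clusters that genuinely correspond to horizontal- and
  vertical-dominated scenes. The two selected category pools are
  activity-matched (trimming at most 30% of extreme-activity members per
  category) so that total population activity carries no category signal
  under the full code — the stimulus-energy control that isolates
  belief-driven modulation. The Fisher discriminant is trained on the same
  representation the observer projects (response magnitudes); the
  log-ratio features serve category discovery only.

What passing tests on this world do *not* show: performance on photographic
corpora (element shapes, occlusion statistics and gray-level distributions
are idealized), spiking variability (responses are real-valued), or
biophysical feasibility of the feedback loop.

## Numerical choices

* **Underflow guard.** Posterior computations run on the logit scale with a
  cap at the double-precision limit (`|logit| <= 690.8`, probability
  `1e-300`). The guard exists only so extreme evidence can never produce
  `NaN`. A materially tighter floor (say `1e-12`) would cap the per-sample
  symmetrized KL near 55 and silently change the cost's optimum toward
  total suppression whenever the classes separate well.
* **Rprop.** Step sizes in `[1e-6, 1]` starting at 0.1, factors 1.2 / 0.5,
  at most 200 iterations; a proposed step is accepted only if it lowers the
  cost (non-finite or worse costs shrink all steps), so reported cost
  traces are non-increasing. Convergence is declared when the relative
  improvement over 10 accepted steps falls below `1e-6`. Initialization is
  Gaussian on `a` (sd 0.3, so `xi` starts near 0.1).
* **Gradient probes.** Central differences with step `1e-3` on `a` for the
  binary tasks, whose cost is smooth. The localization inference term is
  piecewise constant in the correlation-peak position, so its probe is 0.05
  — large enough to cross peak-flip boundaries; a `1e-3` probe would leave
  the optimizer blind to the inference term entirely.
* **Homotopy across the belief grid.** Binary-task tables are built from
  the most informative belief downward, warm-starting each grid point from
  its neighbor's optimum next to a fresh Gaussian start (better of the two
  kept). The cost surface has a suppress-everything basin; the structured
  solution found at high belief remains optimal at lower beliefs but is
  hard to reach from a generic initialization there.
* **Localization training spread.** Each grid entry's training positions
  are scattered with standard deviation `sqrt(sigma_walk^2 + spacing^2/12)`
  rather than `sigma_walk` alone: on a coarse grid, positions anywhere in a
  cell select that entry, and the quantization term keeps the whole cell
  inside the entry's training cloud. Without it, mid-cell targets are
  invisible to the compressed code and tracking enters absorbing failures.
* **Exact shrinkage identities.** `shrink()` short-circuits `xi = 0` to the
  identity and `s = 0` to zero bitwise, and evaluates the general case with
  a log-sum-exp rearrangement around `max(xi, |s|)`, so `|s| = 1000` at
  `alpha = 10` is finite.
* **Ties and degenerate inputs.** Correlation-map peaks break ties to the
  smallest row then column; belief-grid selection breaks ties to the lower
  index; zero-variance series correlate as 0 (flagged) rather than `NA`;
  class models with degenerate spread get a floored standard deviation and
  a flag; k-means clusterings are reseeded up to a retry limit.
* **ROI demo.** The static region-of-interest example replaces the KL term
  with the reconstruction error over ROI pixels on the sparse-coding scale
  (sum of squares over `2 sigma^2`) plus `psi * sum |z|`. At `psi = 0` the
  constraint is inactive and the unshrunk code is returned directly (any
  shrinkage only moves the reconstruction away from the sparse-coding
  optimum). The default sweep `psi in {0, 0.05, 0.2, 0.8}` spans the
  partial-suppression regime where the trade-off is visible.
* **Entropy from logits.** Traces store the predictive belief's logit, and
  uncertainty analyses compute binary entropy from it: saturated beliefs
  would otherwise round to probability 0/1 and collapse every uncertainty
  decile to an exact tie.
* **Grating-mixture fits.** The fixed component width 0.35 of the
  two-Gaussian population-curve fit is interpreted on the orientation axis
  in radians (about 20 degrees); on a unit-normalized axis both components
  would be nearly collinear and the weights unidentifiable.

## Design decisions on open points

* The exact telegraph predictive `p' = (1-h) p + h (1-p)` is the default;
  the low-hazard shortcut `predictive = posterior` is available as
  `approx_predictive = TRUE` (at `h = 0.01` the two differ by less than
  0.02 in probability).
* Measurement noise inside the cost's Monte-Carlo expectation uses common
  random numbers: one noise draw per sample shared between the compressed
  and full branches, which makes `xi = 0` give exactly zero inference error
  and reduces gradient variance.
* Localization's inference error is the closed-form symmetrized KL between
  the per-coordinate Gaussian posteriors of the two branches (equal
  variances, so `(mu_1 - mu_0)^2 / sigma_post^2` summed over coordinates),
  with the observer otherwise relying on point estimates.
* The belief grid uses probabilities `k/K` (`k = 1..K`), so the top entry
  trains on a purely positive-class set.
* Feedback cost is the sample standard deviation of the threshold vector,
  charged at the first step and whenever any component changes.
* H/V cluster selection is automated: per cluster, the circular mean of
  the dominant orientations of atoms whose mean feature exceeds zero,
  taking the clusters nearest 0 and 90 degrees (manual override available).
* The effective-gain fit uses an unconstrained intercept over
  `s in [0, 3]` with 100 grid points.

## Problem sizes

The test suite and the reproduction script run entirely at the scaled
profile: dictionaries learned from 4000 patches for 4 epochs, class models
from 400 samples per state, tables from 250 Monte-Carlo samples per grid
point, closed-loop simulations of 1000-4000 steps, and five-seed
replications for the statistical-structure checks. The full-size profile
reproduces the reference setting (50000 patches, `10^4`/`10^3` training
images per grid point, `10^5`-step simulations) at a proportionally larger
cost.

## A short session

```{r}
library(adaptcode)

fx <- study_fixture(seed = 1)                  # corpus, dictionary, contexts
tab <- build_threshold_table(fx$detection, k = 8,
                             cfg = optim_config(psi = 4, n_mc = 250),
                             seed = 31)
tr_a <- run_closed_loop(fx$detection, tab, T = 2000, seed = 55,
                        mode = "adaptive")
tr_f <- run_closed_loop(fx$detection, tab, T = 2000, seed = 55,
                        mode = "full")
glance(tr_a)                                   # activity, feedback, tracking
glance(tr_f)
autoplot(tr_a)

up <- uncertainty_profile(tr_a, fx$dict)       # activity vs uncertainty
nc <- noise_correlation_experiment(
  generate_patches(1, 16, seed = 3, model = "leaves")[1, ],
  fx$detection, tab, n_rep = 1000)
mean_abs_offdiag(nc$corr_full)                 # ~0 for the full code
```

## Known limitations

* At the scaled patch size the synthetic tasks need the strong template
  contrasts described above; the full-code activity of the detection task
  is therefore state-modulated (object-present frames are cheaper to code),
  unlike the flat premise of the reference setting — the orientation task,
  with activity-matched pools, carries the flat-full-code property instead.
* The full-code localization error is essentially zero on this synthetic
  world (the cross dominates its correlation map), so adaptive-versus-full
  error comparisons are reported as absolute errors rather than ratios.
* Dictionary learning fine-tunes a Gabor-bank initialization; it does not
  rediscover localized features from random initializations within any
  practical budget at these sizes.
* Thresholds change only through table switches, so feedback-cost
  accounting sees discrete events; maintenance costs and transmission
  delays are not modeled.
```
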