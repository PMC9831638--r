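# adaptcode

Normative modeling of dynamic, attention-like modulation in a sensory
population. A bank of model V1 neurons carries a sparse code of
natural-like image patches; every activation passes through a smooth
shrinkage nonlinearity whose per-neuron threshold is set, step by step, by
a Bayesian perceptual observer. The observer chooses the thresholds to
minimize

```
C(xi) = < D_KL^sym[ p(theta | z(xi)) || p(theta | z(0)) ]  +  psi * sum_n |z_n(xi_n)| >
```

— the symmetrized Kullback–Leibler divergence between its one-step
posterior under the compressed code `z(xi)` and under the standard sparse
code `z(0)`, plus an activity cost weighted by the attentional resource
constraint `psi` — averaged over the stimuli it predicts given its current
belief. Precomputed threshold tables over a belief grid close the loop:
encode, shrink, measure, update the belief, select the next thresholds.

The package is aimed at computational-neuroscience work on efficient
coding, top-down gain modulation and belief-driven response variability.
It provides:

- synthetic stimulus generators (1/f Gaussian fields, dead-leaves
  textures, object and cross templates, drifting movies, gratings) and
  PCA preprocessing;
- SparseNet-style dictionary learning and FISTA sparse inference;
- the shrinkage nonlinearity with gain and expected-activity summaries;
- observer models for object detection, target localization and
  orientation estimation (Gaussian class models, conjugate position
  tracking, k-means category discovery, Fisher discriminant);
- Rprop threshold optimization, belief-grid tables, and a static
  region-of-interest compression demo;
- closed-loop simulation with feedback-cost accounting, and analyses of
  the resulting code statistics (sparsity, noise correlations,
  uncertainty profiles, tuning-curve modulation, gain dynamics,
  grating-mixture variability), returned as tibbles with `autoplot()`,
  `tidy()` and `glance()` methods.

## A worked example

```r
library(adaptcode)

fx  <- study_fixture(seed = 1)       # corpus, dictionary, task contexts
tab <- build_threshold_table(fx$orientation, k = 8,
                             cfg = optim_config(psi = 4, n_mc = 250),
                             seed = 31)
tr_a <- run_closed_loop(fx$orientation, tab, T = 1200, seed = 55,
                        mode = "adaptive")
tr_f <- run_closed_loop(fx$orientation, tab, T = 1200, seed = 55,
                        mode = "full")
glance(tr_a)
#> # A tibble: 1 x 7
#>   task        mode         T mean_activity mean_feedback_cost switch_rate mean_posterior_true
#>   <chr>       <chr>    <int>         <dbl>              <dbl>       <dbl>               <dbl>
#> 1 orientation adaptive  1200          2.29              0.598       0.24                0.820
glance(tr_f)$mean_activity
#> [1] 145.6
```

The adaptive code spends about 2% of the standard sparse code's activity
(2.29 plus 0.60 of feedback cost, versus 145.6) while the observer's
posterior still assigns 0.82 on average to the true environmental state. `autoplot(tr_a)`
shows the belief tracking the scripted state switches with activity
concentrated at uncertain moments; `uncertainty_profile(tr_a, fx$dict)`
quantifies that activity rises with the observer's uncertainty, while the
same analysis of `tr_f` is flat.

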