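---
title: "Neural flexibility from dynamic functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural flexibility from dynamic functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroflex)
```

## The model

neuroflex estimates *neural flexibility* — how readily a brain region
changes its functional-module allegiance over the course of a resting-state
fMRI scan — and carries that estimate through group statistics and
predictive models. The pipeline operates entirely on parcellated region
(ROI) time series; image-domain preprocessing is out of scope.

The stages, each an exported function:

1. **Sliding-window connectivity** (`build_layer_stack()`). Pearson
   correlations between all `choose(R, 2)` region pairs are computed in
   half-open windows `[s, s + width)` (0-based; default width 30 volumes,
   step 1). Each correlation receives a two-sided p-value from the exact-t
   reference `t = r sqrt((n-2)/(1-r^2))` with `n - 2` degrees of freedom,
   and Benjamini–Hochberg FDR control is applied *within each window*
   across all pairs (for a 264-region parcellation this is the familiar
   family of 34,716 connections). Non-retained entries are zeroed;
   retained correlations keep their value.
2. **Multilayer network** (`multilayer_network()`). The thresholded
   windows become layers; every node is coupled to itself in ordinally
   adjacent layers with weight `omega`.
3. **Community detection** (`generalized_louvain()`,
   `detect_communities()`). Multilayer modularity
   $$Q = \frac{1}{2\mu} \sum_{ijsr}\left[\left(A_{ijs} -
   \gamma\frac{k_{is}k_{js}}{2m_s}\right)\delta_{sr} +
   \delta_{ij}C_{jsr}\right]\delta(g_{is},g_{jr})$$
   is maximized by a greedy two-phase (move + aggregate) optimizer over
   all node–layer copies. Because the optimizer is greedy and seeded, the
   detection is repeated (`n_reps`, reference value 100) and all
   community-based measures are averaged over repetitions.
4. **Flexibility** (`node_flexibility()`, `flexibility_profile()`).
   For node *i*, `f_i = n_i / N`: the number of adjacent-window community
   changes divided by `N = W - 1` possible changes. System-level values
   are unweighted means over a system's nodes, the whole-brain value the
   mean over all nodes; stability is `1 - flexibility` at every level.
5. **Group statistics** (`contrast_groups()`). Ordinary least squares of
   the flexibility feature on a group indicator plus covariates (age, sex,
   mean framewise displacement, site). The single whole-brain ADHD–TDC
   comparison is reported at raw p; system and node families are
   BH-corrected across their units; the three medication comparisons
   (medicated vs unmedicated ADHD, unmedicated vs TDC, medicated vs TDC)
   form their own family of three.
6. **Prediction** (`rank_importance()`, `top_n_search()`,
   `evaluate_model()`). Gradient-boosted trees rank regions by split-gain
   share; the top-N prefix is swept and each candidate set scored by
   repeated stratified k-fold cross-validation (reference: tenfold, ten
   times); the selected set is refit on the training site and evaluated
   once on the held-out site.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `width`, `step` | 30, 1 volumes | sliding-window geometry |
| `alpha` | 0.05 | within-window FDR level |
| `negatives` | `"zero"` | drop significant negative correlations |
| `gamma` | 1 | intralayer resolution (larger = smaller modules) |
| `omega` | 1 | interlayer coupling (larger = more persistent labels) |
| `n_reps` | 100 | detection repetitions averaged |
| `n_folds`, `n_repeats` | 10, 10 | cross-validation shape |

`gamma` and `omega` default to 1 because the underlying study reports
neither; both are exposed everywhere and the tests verify the qualitative
effect of `omega` (stronger coupling monotonically suppresses flexibility).
The negative-weight policy is likewise genuinely open: the configuration
null model is designed for nonnegative weights, so the default removes
significant negative correlations; `negatives = "retain"` keeps them.

Boosted-tree hyperparameters are fixed and recorded
(`xgb_defaults()`: eta 0.3, depth 3, 50 rounds, no subsampling,
single-threaded) — shallow, deterministic settings rather than a tuned
configuration, since the reference tuning table is not public.

## The synthetic cohort generator

`simulate_cohort()` emulates the *assumptions* the analysis rests on, not
fMRI physics. Each subject switches between `n_states` discrete
connectivity states; a state is a module partition, and signal rows are
drawn i.i.d. from a multivariate normal whose correlation matrix has
`rho_in` (default 0.6) within modules, `rho_out` (0.1) between, unit
diagonal. The per-boundary switch probability is the planted ground truth:
TDC 0.10, unmedicated ADHD 0.04, medicated ADHD 0.09 by default, so the
generator plants the direction the statistics should recover (ADHD switches
less; medicated sits near TDC). Individual subjects jitter around their
group baseline (`switch_rate_sd`, default 0.02): severity is a continuum,
and without between-subject rate variation a within-group severity
regression would have nothing to predict. The packaged power and
calibration studies set `switch_rate_sd = 0` to test at exactly the stated
group rates. A severity score is generated as
`severity_slope * (-switch_rate) + noise` — higher severity, lower
switching — on a single synthetic scale. Covariates (age, sex, motion
surrogate `mean_fd`, site) are drawn independently and have zero effect on
the switch rate by default; `covariate_effects` can plant confounding.

What the generator deliberately omits: hemodynamics, temporal
autocorrelation within a state, scanner noise and real head motion,
site-specific scale differences in severity. Passing tests therefore show
that the pipeline recovers planted dynamic modular structure under the
model's own assumptions — not that it is robust to everything real fMRI
contains.

Determinism: every draw descends from `master_seed` (subject seeds are
drawn once from it), so one integer reproduces a cohort bit-for-bit.

## Numerical choices

* **Fast FDR path.** Within a window, BH on exact-t p-values at fixed `n`
  is equivalent to a step-up rule on sorted `|r|` against a precomputed
  critical sequence (`qt` evaluated once per stack, not two t-CDF calls
  per pair per window). The tests verify this path against the literal
  p-value + step-up route.
* **Greedy moves.** A node–layer moves only for a strictly positive
  modularity gain (tolerance 1e-12); sweep order is reshuffled every pass
  from the run seed; ties keep the first-encountered candidate. The
  optimizer's randomness is a small deterministic generator, so identical
  seeds give identical partitions on any platform.
* **Aggregation order.** Repetition averaging happens at the node level
  before any spatial aggregation; whole-brain equals the node-count
  weighted mean of system means, an identity the tests assert.
* **Degenerate inputs.** Constant columns within a window make their
  pairs undefined: flagged and treated as non-retained, never fatal. A
  window retaining no edges contributes no intralayer quality but keeps
  its coupling terms. Zero-variance features in a group contrast yield an
  NA row rather than aborting a cohort-level analysis.
* **Selection bias.** The default top-N search ranks features once on the
  full training cohort (the reference procedure); since the ranking has
  seen all training labels, CV estimates at small N are optimistically
  biased. `nested = TRUE` recomputes the ranking inside every training
  fold at k times the cost.

## Problem sizes used by the test suite

The packaged studies are sized for a single CPU. The parameter-recovery
power study uses 20 replicate cohorts of 40 TDC (switch rate 0.10) and 40
unmedicated ADHD (0.04) subjects, 50 regions, 120 volumes, and 20 detection
repetitions per subject, expecting a negative whole-brain contrast at
p < 0.05 in at least 80% of cohorts. Type-I calibration uses 100 cohorts
at reduced scale (30 regions, 80 volumes, 20 per group, 10 repetitions,
equal switch rates), checking the rejection rate against the 95% binomial
band around 0.05. Exhaustive-enumeration oracles cover every multilayer
instance up to 6 node–layer copies (Bell(6) = 203 partitions).

## Known limitations

* The generator's i.i.d.-within-state rows understate the temporal
  autocorrelation of real BOLD signal, so absolute flexibility values are
  not comparable to values from clinical data; only contrasts and
  recovered orderings are meaningful.
* Greedy modularity maximization has no optimality guarantee; the package
  mitigates with repetitions and seeds but different `omega`/`gamma`
  choices change absolute flexibility levels.
* The severity model is linear on one synthetic scale; cross-site clinical
  scale harmonization is explicitly out of scope.
* Medication status is a planted label, not a pharmacological model.

## A short worked example

```{r example, eval = FALSE}
cfg <- synth_config(
  n_per_group = c(tdc = 20, adhd_unmedicated = 20, adhd_medicated = 10),
  n_regions = 30, n_timepoints = 90, master_seed = 7)
res <- run_pipeline(cfg, n_reps = 10, n_folds = 5, n_repeats = 2,
                    n_grid = c(1, 5, 10, 30), seed = 7)
res$contrasts$whole_brain
glance(res$classification$search)
plot_flexibility_groups(res$flexibility, res$cohort$subjects)
```
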