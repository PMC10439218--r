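---
title: "Mapping water access points from presence-only registries: models, scaling, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping water access points from presence-only registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Registries of drinking-water access points (boreholes, piped connections,
springs, wells, rainwater harvesting, surface-water intakes) are
presence-only: a record proves a point exists in a cell, but the absence of
a record proves nothing. aquamap treats the estimation problem the way
species-distribution modellers treat occurrence data. Divide the study area
into 1 km^2 cells, attach a vector of feature layers `z` to each cell, and
compare the feature distribution at presence cells, `f1(z)`, with the
distribution over the whole area, `f(z)`. The ratio

    p* = f1(z | y = 1) / f(z)

is the *relative probability* of presence. The true probability
`P(y = 1 | z)` equals `p*` times the prevalence, which presence-only data
cannot identify; following the standard convention we assume prevalence
0.5 wherever a probability-scale output is needed.

Three estimators of `p*` are provided:

* **MaxEnt** — a Gibbs model `f1(z) = f(z) exp(alpha + beta' h(z))`, where
  `h` stacks the classical basis classes (linear, quadratic, product,
  hinge, threshold, categorical indicators) and `beta` is found by
  maximizing the L1-penalized mean log density over presences.
* **MLP** — a multi-layer perceptron with a logistic output unit trained by
  minibatch Adam on the binary log loss, presences against sampled
  background cells.
* **MLP with weighted background** — the same classifier, but the
  background is drawn with probability proportional to the inverse of each
  cell's *prior expected* number of points (population-proportional), so
  background cells resemble true absences; the population-density feature
  is removed from this model so it cannot degenerate into a people
  detector.

Downstream of the classifiers, the relative-probability surface is scaled
into absolute expected counts per cell using household-survey access shares
(`scale_to_counts()`), and validated against household usage reports
(`compare_usage_groups()`).

## The estimation chain, end to end

1. **Screening** (`correlation_screen`). Pairwise association over masked
   cells: Pearson's R for numerical pairs, Cramer's V for categorical
   pairs, eta-squared for mixed pairs. Defaults `r_max = 0.7`,
   `v_max = 0.65`, `eta_max = 0.7` bracket the associations at which real
   analyses prune layers. When a pair exceeds its threshold the member with
   the larger mean absolute association to all other layers is dropped
   (ties drop the later layer), which preserves maximal independent
   information and is deterministic; the screen is idempotent.
2. **Split** (`split_presences`). 70% of presence records train, 30% are
   held out. The split is record-level — two points in one cell may land on
   both sides, mirroring point-level registry splits — with a
   `by_cell = TRUE` option for strict leakage control.
3. **Background** (`sample_uniform_background`,
   `sample_weighted_background`). Background cells are drawn from masked
   cells carrying no recorded presence *of any type*; the sample is
   `ratio` times the presence count (default 4, i.e. 100 presences give
   400 background cells). Draws are without replacement while the pool
   lasts, then with replacement plus a warning — preserving the requested
   ratio matters more than uniqueness, because the ratio drives the
   threshold metrics. For the weighted scheme, the prior expectation
   `np_i = P_total_j * pop_i / sum(pop in stratum j)` is computed within
   urban and rural strata separately (the pooled form sits behind
   `stratified = FALSE`); selection weights are `1 / np_i`, and
   zero-expectation cells receive the maximum finite weight rather than
   infinity.
4. **Training** (`fit_maxent`, `fit_mlp`, `hyperparameter_search`).
5. **Scaling** (`persons_per_point` -> `average_persons_per_type` ->
   `total_expected_presences` -> `scale_to_counts`).
6. **Evaluation** (`tpr`, `fpr`, `auc`, `sensitivity_sweep`) and survey
   validation (`compare_usage_groups`, `two_proportion_ztest`,
   `min_sample_size`).

## MaxEnt: numerical choices

The fitted objective is

    max over (alpha, beta):  mean_presences (alpha + beta' h(z_i))
                             - sum_j lambda_j |beta_j|

with `alpha = -log sum exp(beta' h(z))` taken over the *study-area sample*:
the background rows pooled with the presence rows. The normalization
constraint in the model definition integrates the fitted density over the
whole study area, and the empirical stand-in for the study area must
therefore contain the presence cells. This choice also keeps the objective
bounded: if the normalizer ranged over background cells only, any presence
whose features fall outside the background's support would let the density
concentrate on it without limit, and the optimizer would crawl along an
unbounded ridge until the iteration cap.

Other numerical decisions:

* **Feature scaling.** Numerical features are min-max scaled to [0, 1]
  using the pooled presence + background rows, again so no fitting-time
  basis value escapes [0, 1]. At prediction time, values outside
  [-0.5, 1.5] after scaling are clipped with a warning.
* **Penalty.** `lambda_j = lambda_scale * mult_j * sd_j / sqrt(m)`, where
  `sd_j` is the basis column's standard deviation over the pooled sample,
  `m` the presence count, and `mult_j` is 2 for hinge and threshold terms
  (the flexible classes) and 1 otherwise. Scaling by `sd_j` makes the
  penalty equivariant to feature scale — without it, low-variance columns
  are under-penalized and the probability surface collapses toward the
  prevalence. `lambda_scale = 1` by default and configurable; published
  MaxEnt defaults are version-specific, so this is a package choice, not
  an inferred one.
* **Optimizer.** Proximal gradient ascent with soft-thresholding and a
  backtracking line search (step doubles after success, halves on
  failure); monotone by construction, stopped when the objective improves
  by less than `tol = 1e-8` or after `max_iter = 3000` steps. Separable
  data with `lambda_scale = 0` is genuinely unbounded; the guard is the
  iteration cap plus a warning.
* **Zero-variance basis columns** are dropped with a warning before
  fitting; hinge/threshold knots sit at `j / (knots + 1)` on the scaled
  axis (4 knots per feature by default).
* **Calibration.** The probability-scale output is
  `p* = plogis(log q + log c)` with `c` solved (by `uniroot`, in log
  space) so that the mean over the *background rows* equals the assumed
  prevalence 0.5. With `beta = 0` every cell scores exactly 0.5.

The independent check on all of this is a brute-force grid search of the
same objective on one-feature problems; the fitted coefficient agrees with
the grid optimum to better than 1e-3 (see `test-acceptance.R`).

## MLP: numerical choices

Architecture and training mirror the sklearn MLPClassifier conventions the
field uses: Glorot-uniform initialization, hidden activations from
{identity, logistic, tanh, relu}, a single logistic output unit, minibatch
Adam (beta1 0.9, beta2 0.999, eps 1e-8, batch 200 by default), inputs
standardized on the training rows, and an elastic-net weight penalty
`alpha * (l1_ratio * sum|W| + (1 - l1_ratio) * 0.5 * sum W^2) / n` — the
`l1_ratio` in the hyperparameter grid is read as this mixing weight.
Learning-rate schedules: `constant`; `invscaling` (eta0 / sqrt(epoch));
`adaptive` (divide by 5 after two epochs without improvement, stop when
the rate falls below 1e-6). Early stopping ends training after 10 epochs
without a `tol = 1e-4` improvement of the full-sample penalized loss;
hitting `max_iter` first returns the model with a warning and the final
loss recorded. Everything is reproducible from the seed.

`hyper_search_space()` reproduces the reference grid — 22 hidden-layer
layouts from (5) to (100, 100), four activations, three schedules,
`l1_ratio` in {0, 1}, epoch budgets {500, 1000, 2500} — sampled uniformly
at random for 200 trials with stratified 5-fold cross-validation scored by
validation log loss. Uniform sampling replaces the adaptive searcher used
in practice because it is reproducible and, at 200 trials over this grid,
covers it densely; ties go to the first trial. When the held-aside 30%
evaluation partition is passed in, the winning configuration's k fold
models are scored on it and the best one is returned — selecting among
fold models requires that partition, which is why
`hyperparameter_search()` accepts it explicitly.

Permutation importance shuffles each feature (all one-hot columns of a
categorical layer jointly) and reports the mean log-loss increase divided
by the unpermuted loss. The same permutations are reused for every feature
group, which makes the result exactly invariant to column order.

## Scaling relative probabilities to counts

With cell population `pop_i` and the total number of recorded points of
all types `n_i`, `s_i = pop_i / n_i` estimates persons per point in cells
with registry data; the per-type, per-stratum persons-per-source is the
unweighted mean of `s_i` over cells where the type occurs (a
population-weighted variant sits behind a flag). Stratum access shares
convert to expected totals `y = share * pop_stratum / s`, and the map is
scaled within each stratum as `y_i = y_total * p*_i / sum(p*)`, conserving
totals exactly and ignoring the presence threshold. Two stated assumptions
carry through from the estimator's definition: cells with registry data
are taken as completely surveyed, and co-located types share the cell's
population.

## What the synthetic generator emulates — and what it does not

`generate_world()` produces: smoothed Gaussian numerical layers;
quantile-thresholded categorical layers (3 codes); a clustered log-normal
population surface (median 8 persons/km^2 by default, heavy-tailed), with
the top 15% of cells classified urban; per-type latent suitability
defined by named layer combinations (the defaults give one linear type,
one driven by a rainfall x poverty interaction, one mixed); and Poisson
point counts whose expectation allocates each cell's population across
types by a softmax over the suitabilities, divided by the type's true
persons-per-point. Shares are then the served persons by type, normalized
within stratum — so they sum to one exactly, and the share table, the
population surface and the counts are mutually consistent, which is what
makes the scaling chain recoverable. The registry is complete by default
(`detection_rate = 1`); `observe_presences()` thins cells binomially and
can impose distance-decay sampling bias around a random survey centre. A
detected cell contributes one record per true point, so record
multiplicity carries the per-cell point counts the persons-per-source
estimator needs.

The generator deliberately does **not** emulate: real geography or
projections, registry schema beyond (type, cell), survey non-response,
type-dependent detectability, or temporal dynamics. Passing tests on these
worlds therefore demonstrates the correctness and internal consistency of
the estimation chain, not its accuracy on any real registry.

Default study conditions, chosen once as desk-scale analogues of a
national analysis: a 60 x 60 grid of 1 km cells, 5 numerical + 2
categorical layers, 3 access types with true persons-per-point of about
75 (borehole), 40 (piped), 130 (spring) and a 5% urban/rural contrast —
values in the range national estimates report. Under these defaults the
registry holds a few hundred presence records per type, roughly the
regime of the sparser registry types.

Two derived study conditions are used by specific checks:

* **Recovery conditions** (persons-per-source and totals): a dense world
  (`pop_meanlog = log(1000)`, `pop_sdlog = 0.5`) with a uniform true
  persons-per-point of 40. Equal persons across types is the estimator's
  own identifying assumption: `pop_i / n_i` mixes the types co-located in
  a cell, so with strongly type-varying persons the estimate for the
  smallest-persons type is biased upward by design, even under strong
  spatial segregation. The dense, equal-persons world validates the chain
  where its assumption holds; the mixed-type bias is the estimator's
  documented approximation, not an implementation property. An `allocation_sharpness` knob is available for studying the
  segregation effect.
* **Sweep and model-ordering conditions** use the data-rich
  interaction-driven type (`piped_water`), whose ~700 training records
  keep the ratio sweep's smallest training set meaningful and whose
  rainfall x poverty product term lies outside a product-free MaxEnt
  basis.

## Evaluation

TPR is the fraction of held-out presence scores *strictly* above the
threshold `theta` (default 0.3), FPR the same fraction among background
scores; ties at the threshold count as non-presence. Because background
cells may hold undetected presences, the best attainable FPR can exceed
zero. AUC is the rank-based Mann-Whitney statistic with ties counted one
half. The contrast the sweep makes executable: AUC is invariant under any
strictly monotone transform of the scores, while TPR/FPR at fixed theta
are not — so AUC cannot see the scale shifts that a changing
background:presence ratio induces. In `sensitivity_sweep()` the presence
split is fixed across ratios, the training background is redrawn per
ratio, and the evaluation background has *fixed* size (`eval_ratio`
times the test presences, default 4; the reported analyses use 10) so the
AUC column is comparable across rows; the evaluation background is drawn
independently of the training background (reuse is a flag).

One spatial-recovery caveat worth stating: on realistically sparse worlds
(95% of cells hold no point of a given type), the Spearman correlation
between *any* predicted surface and the realized Poisson counts is capped
well below 1, because zero-count cells tie: the true suitability surface
itself stays far from 1 against the counts it generated. The end-to-end
test therefore computes this oracle ceiling and requires the fitted map
to recover at least half of it, rather than an absolute correlation that
no estimator could attain.

## Survey statistics

`compare_usage_groups()` assigns each household its cell's predicted
count (households sharing a cell are tied by construction), then gates on
normality: a one-sample Kolmogorov-Smirnov test of each group against a
normal with the group's moments; if either group departs at p < 0.1 the
groups are compared by a two-sided Wilcoxon rank-sum test (normal
approximation with tie correction; exact for n < 20 without ties),
otherwise by a two-sample t-test. Empty or zero-variance group pairs are
flagged untestable rather than tested. The two-proportion z-test uses the
pooled-proportion form and reports both the two-sided and the directional
p-value, since survey reports often cite the directional one.

`min_sample_size()` evaluates the finite-population chi-square guideline.
With the canonical inputs (chi2 = 3.841, population 50 000 households,
proportion 0.5, accuracy 0.05) the formula gives 381.2 (ceiling 382);
survey manuals commonly print 380 for these inputs, a discrepancy that
traces to rounded source tables. The function returns the exact formula
value and its ceiling and leaves the rounding convention to the caller.

## Limitations

* MaxEnt and the MLP are the only model classes; no bias corrections
  beyond the weighted background scheme (no target-group background or
  thinning).
* The persons-per-source chain inherits the completeness assumption of
  the registry and the co-location mixing bias described above; neither is
  "corrected", both are surfaced.
* Grid geometry is user input: no projections, geodesy, or GeoTIFF I/O —
  the stack I/O is the CSV/JSON layout documented in `export_stack()`.
* Problem sizes in the tests and the acceptance script are desk-scale
  (60 x 60 worlds, reduced search spaces, reduced epoch budgets), chosen
  as the package's default study conditions; the full reference grid
  remains the default of `hyper_search_space()`.
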