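---
title: "Methods: rich versus lazy learning and task geometry in richlazy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rich versus lazy learning and task geometry in richlazy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Animals and artificial networks solving several tasks with shared inputs
must keep the tasks from interfering. `richlazy` studies a minimal version
of this problem: a 5 x 5 grid of Gaussian-blob stimuli is classified along
its x coordinate in one context and its y coordinate in the other, with a
signed reward from -2 to 2. A single-hidden-layer ReLU network (25 pixel
inputs + 2 one-hot context inputs -> 100 hidden units -> 1 linear output)
is trained by minibatch SGD on the mean squared error between its output
and the reward.

The package's central contrast is the *initial weight scale* `sigma0`, the
standard deviation of the Gaussian from which the input-to-hidden weights
are drawn (readout weights always have variance 1/100; biases start at
zero). Small `sigma0` (0.01) yields *rich* learning: the hidden
representation restructures, irrelevant feature dimensions are compressed
within each context, and the two tasks come to occupy orthogonal
low-dimensional manifolds. Large `sigma0` (3) yields *lazy* learning: the
hidden representation stays close to its random initialization (a
grid-like, high-dimensional embedding of the inputs) and learning
concentrates in the readout.

## Representational similarity analysis

Hidden (or simulated neural) activity is summarised by a representational
dissimilarity matrix (RDM) of pairwise Euclidean distances between the 50
condition patterns (`euclidean_rdm()`), or by a cross-validated Pearson
distance across runs with within-run cells set to missing
(`crossval_pearson_rdm()`).

Seven candidate model RDMs are generated from explicit coordinate
constructions (`model_feature_matrix()`): a *grid* (both features retained
on two context sheets at unit separation), *orthogonal* (each context
retains only its relevant feature), *parallel* (the orthogonal model with
one task manifold rotated by 90 degrees onto the other's axis),
*rotated grid*, the single-feature *branchiness* and *leafiness* controls,
and a *diagonal* projection onto (b + l)/sqrt(2). Neural RDMs are
regressed on model RDMs after vectorising the lower triangle and z-scoring
both sides (`rdm_regression()`); z-scoring uses the population (n)
standard deviation so that results are bit-comparable with a
normal-equations oracle.

The *parameterised* geometry model (`param_geometry()`,
`fit_param_geometry()`) spans this model space continuously with six
parameters: four compressions (relevant/irrelevant per context, in [0,1]),
a rotation of the context-A manifold (degrees in [-90, 90]), and a
context-offset multiplier. At its limits it reproduces the grid,
orthogonal and parallel models to machine precision, which the test suite
asserts. Fitting minimises raw squared error between lower triangles with
L-BFGS-B from random starts inside the bounds. Because the published
procedure averages "over 1000 independent runs with random starting
values" and it is ambiguous whether the estimate is the average of
per-start optima or the best start, both are returned (`$estimate` and
`$best`); the per-start table is retained. Two further choices are ours:

* the objective compares raw distances on the model's unit-grid scale, so
  RDMs of arbitrary scale (trained hidden layers) are first rescaled to
  the grid model's root-mean-square distance with `normalize = "rms"`;
  planted-geometry recovery uses `normalize = "none"` and is exact;
* the *compression index* is reported as `log(compr_irrel / compr_rel)`
  averaged over contexts, so that positive values mean the irrelevant
  dimension is more compressed (the rich-regime signature). Compressions
  below 1e-6 are clipped with a warning.

## Unit-level gating analyses

ReLU units are classified from their 50-condition activations
(`classify_units()`): *dead* (no activation above `tol = 1e-8` anywhere),
*task-specific* (active in exactly one context — the nonlinear gating
signature), *task-agnostic* (active in both). The tolerance guards
accumulated floating-point error; ReLU produces exact zeros in exact
arithmetic. Companion analyses measure the Pearson correlation between
the two context weight vectors (`context_weight_correlation()`; strongly
negative for task-specific units in rich networks), re-evaluate the
network with a sub-population clamped to zero (`ablate_and_eval()`), and
split accuracy by congruency (`congruency_accuracy()`; a condition is
congruent when its two feature levels share a sign, conditions with a zero
feature are excluded — the term is used without a formula in the
literature, so this definition is the package's own).

For trial-wise rate data (the 6 motion x 6 color x 2 context
pseudo-population design), `unit_selectivity_regression()` fits each unit
on four context-split predictors, applies Benjamini-Hochberg FDR at 0.05
across all unit-coefficient tests (the correction procedure is unnamed in
the source literature; BH is the field default), and categorises units by
which coefficients survive. `unit_response_model_fit()` regresses
magnitude-difference RDMs (absolute differences of mean responses) on
*factorised* (response follows the context-relevant feature) versus
*linear* (response follows b + l regardless of context) models.

## Behavioral model

`choice_probability()` implements a four-parameter psychophysical model: a
linear category boundary through the origin at angle phi (parameterised by
its normal: d = cos(phi) b + sin(phi) l), a logistic choice function with
slope s and inflection offset o, and a symmetric lapse floor/ceiling
(p = lapse/2 + (1 - lapse) logistic(s (d - o))). The exact functional form
is a declared convention — the source literature defers it to earlier work
— and the fit objective is the sum of squared differences between
empirical and predicted per-cell plant probabilities, minimised by
multi-start bounded search. The *angular bias* is the absolute angular
disparity to the ground-truth boundary (0 degrees in context A, 90 in
context B); a diagonal-rule chooser is 45 degrees off in each context.

Choice matrices are also summarised geometrically
(`fit_factorised_linear()`): a behavioral RDM of absolute differences in
p(plant) is regressed on factorised and linear model RDMs; the factorised
beta is the *axis-alignment score*. `diagonal_strategy_accuracy()` scores
the context-blind b + l > 0 strategy by strict sign agreement with the
relevant feature over the 40 conditions with a nonzero relevant feature:
28/40 = 70%. Strict sign agreement matters: the diagonal score ties at
zero on anti-diagonal stimuli, and counting those ties as correct for
negative targets would give 32/40 instead. `sign_accuracy()` applies the
same convention throughout (for continuous network outputs the two
conventions coincide almost surely).

## The recurrent gating model

`simulate_gating_rnn()` integrates a hand-wired four-unit firing-rate
network (preferred/anti-preferred motion and color units) with unit-weight
self-recurrence, dh/dt = -h + relu(h + Wx x + Wu u), by forward Euler from
h(0) = 0. We store the state post-update; non-negativity enters only
through the rectifier inside the dynamics, which is the reading of the
printed equation we adopt (the equation admits a second reading in which
the rate itself is clamped). Context acts purely subtractively: motion
units are inhibited by the color context and vice versa with strength `w`.
The stimulus profile a e^(-t/tau) + b is a sharp onset transient decaying
to a plateau for 0 < t <= t_x; the context pulse lasts until t_u > t_x.

The profile constants are unstated in the source description, so the
defaults (`a = 2`, `b_profile = 0.2`, `tau = 0.3`, `t_x = 1`, `t_u = 2`,
`w = 0.5`, `dt = 0.005`) were chosen once so that the onset transient
exceeds the inhibition (irrelevant units respond early — grid-like
geometry) while the plateau falls below it (irrelevant units decay to
silence — orthogonal geometry late). `windowed_geometry()` quantifies
this by regressing per-window RDMs over a 6 x 6 x 2 stimulus grid on grid
and orthogonal models; with `w = 0` the early and late geometries are
identical and never orthogonalise, which is the mechanism's necessity
check. Halving `dt` changes endpoint states by under 2%.

## Synthetic data

All inputs are generated in code; no external data are consumed.

* `make_condition_grid()` renders the 50 task conditions. The blob width
  (0.8 grid steps) makes neighbouring blobs overlap while opposite
  corners are nearly orthogonal. Each image is normalised to unit peak
  ("max"); unit sum is available as config (see Limitations).
* `gen_planted_patterns()` embeds any model geometry into n units by a
  seeded random orthonormal map (QR of a Gaussian matrix) — an isometry,
  so noiseless RDMs equal their target model RDM exactly — plus i.i.d.
  Gaussian noise per run.
* `gen_synthetic_choices()` draws binomial responses from the
  psychophysical model on the 2 x 5 x 5 design.
* `gen_pseudo_population()` simulates balanced trial-by-unit rates for the
  72-condition design from mixtures of task-specific (context-gated, with
  a 1/sqrt(2) context baseline and balanced tuning signs, so that the
  noiseless condition means embed the orthogonal geometry exactly),
  task-agnostic, single-feature and untuned units.

What the generators do *not* emulate: haemodynamics and measurement noise
structure of BOLD, spike-count statistics, session-to-session drift, or
any property of the deposited human/monkey datasets. Passing tests therefore
validate the analysis machinery, not claims about those datasets.

## Training regimes and problem sizes

`train_config()` defaults to the published settings (learning rate 0.001,
batch 50, 10000 iterations, minibatches drawn uniformly with replacement
with the two contexts interleaved; plain SGD with analytic gradients; the
ReLU subgradient at 0 is taken as 0). Under this package's mean-reduced
gradient convention, networks initialised at `sigma0 = 0.01` have not yet
met the convergence criterion after 10000 iterations (running-mean loss
below 0.01 for five consecutive checkpoints, recorded every 100
iterations). Every regime-level analysis is therefore performed at the
regime's convergence point: lazy networks train at the published
settings, which they converge well within, while rich networks train at
learning rate 0.002 for 20000 iterations — the smallest budget at which
they meet the criterion. Cohorts of 20 networks per regime take on the
order of five minutes on one CPU. The speed ordering (lazy converges several
times faster than rich) is asserted as an ordering only, since the
convergence criterion itself is this package's convention.

The auxiliary RDM loss (`rdm_beta`) penalises the squared difference
between the hidden layer's Gram-derived RDM — which is on the *squared*
Euclidean distance scale — and a target RDM supplied on the same scale;
each iteration then passes all 50 conditions through the network.
With matched hyperparameters, orthogonal and grid targets reach ceiling
accuracy with a close RDM fit, while a parallel target leaves a several-
fold larger RDM misfit in a single hidden layer; an optional second
hidden layer is supported for exactly this experiment.

## Known limitations

The stimulus normalisation is the dominant free condition of the whole
simulation, and the published description does not pin it down. The
package's default (unit-peak images) makes the stimulus drive comparable
to the context drive, which keeps every lazy-regime phenomenon correct:
lazy hidden layers are grid-like (grid beta > orthogonal beta),
high-dimensional, and not partitioned by context at initialisation. Under
this default, converged rich networks show the full qualitative gating
phenotype — anticorrelated context weights, orthogonal geometry, strong
irrelevant-dimension compression — but only ~20-25% of hidden units are
task-specific in the *exact-zero* sense, and ablating them leaves
accuracy near ceiling rather than dropping it to the diagonal-rule level.
With weak (unit-sum) stimuli the exact-zero fraction reaches ~50% and the
ablation effect appears, but the lazy regime is then corrupted (context
partitioning is already present at initialisation). We chose the
configuration that keeps the rich/lazy contrast — the package's central
object — internally consistent, and report the gating quantities as they
come out. Counts of principal components at fixed variance thresholds
inherit the same sensitivity: under the default conditions rich networks
need ~4-5 components for 95% variance and lazy networks ~13, and the
truncation analysis shows the same rich/lazy ordering at somewhat
different absolute counts than published.

`svd_spectrum()` does not centre by default (the raw stimulus-by-unit
matrix is decomposed, matching the published description); column
centring is a flag, and the reported component counts depend on it.
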