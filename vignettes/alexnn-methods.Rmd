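---
title: "Models and methods behind alexnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alexnn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alexnn)
```

`alexnn` implements the statistical pipeline used in questionnaire
studies of alexithymia: instrument scoring, distributional and
collinearity diagnostics, AIC-guided backward regression, bootstrap
mediation, a deep tanh backpropagation network, and subgroup discovery
by clustering the network's deepest hidden layer.  This vignette records
the models, the conventions, and the design decisions that were
genuinely open — the things a maintainer or reviewer would want stated
rather than reverse-engineered from code.

## The synthetic cohort generator

No raw data accompanies most published surveys of this kind, so the
package treats the generator as a first-class, tested module rather than
a test fixture.  `generate_table()` draws, per participant:

* a latent group label from the configured mixture weights;
* 16 correlated continuous predictors from a within-group Gaussian with
  that group's mean profile (on the z scale) and covariance;
* gender as Bernoulli(0.5), encoded 0/1 with 1 = male — surveys in this
  area recruit roughly balanced samples, and a balanced indicator also
  exercises the excess-kurtosis ≈ −2 edge case in the diagnostics;
* three alexithymia subscales from planted linear coefficients, group
  intercept offsets, group-specific slopes (interactions), an optional
  mediation path, and Gaussian noise; the TAS total is their sum.

Latent z scores are then mapped onto instrument scales
(`default_variable_scales()`), clipped to the admissible ranges and
rounded where instruments produce integers.  Clipping biases the
realized moments of strongly shifted profiles toward the center; this is
accepted and documented, because the bounded, discrete marginals are
exactly what real questionnaire data look like.  `unit_scales()` with
`apply_bounds = FALSE` disables the mapping for method studies where
truncation would obscure a planted effect — the mediation calibration
study uses this mode so the OLS estimands equal the planted paths
exactly.

The default correlation structure is a two-factor model (a
general-distress factor over the DASS subscales, inflexibility and
negative affect, and an interoception factor over the MAIA-2 subscales
and self-as-context, with signs matching what these instruments
typically show).  A factor construction was chosen over a literal target
matrix because it is guaranteed positive definite and makes the sign
structure auditable; it is loosely calibrated, not an estimate of any
particular dataset.

`separated_group_specs()` places group mean profiles at scaled Hadamard
sign patterns, mapped through the Cholesky factor of the shared
covariance so that **every** pairwise Mahalanobis distance equals the
requested separation exactly.  Spreading the separation across all
predictors (rather than a few axes) keeps per-variable shifts small
enough to survive clipping; concentrating the same distance on single
variables loses most of it to the instrument bounds.

Three canonical study configurations freeze the conditions used by the
validation suite: `subgroup_study_config()` (three equidistant groups,
distance 8, each with its own elevated subscale and noise SD 0.4),
`interaction_study_config()` (the same groups with group-specific
slopes of ±1.2 on different predictors for one subscale), and
`mediation_study_config()` (homogeneous cohort, independent predictors,
pure-noise subscales, planted `m = a·x + e` and `y += b·m + c'·x`).
One RNG stream per table, seeded from the configuration; the caller's
RNG state is never disturbed.

What the generator does **not** emulate: item-response-theory response
processes, missing data (complete-response designs are standard for
these online surveys), floor/ceiling asymmetries beyond clipping, and
measurement error structure within subscales.  Tests passing on this
generator demonstrate that the *methods* are correct and calibrated
under known truth — not that any particular empirical finding holds.

## Scoring

Scoring is driven by an explicit `scoring_map`: item identifiers,
response ranges, subscale partitions, reverse-keyed items, sum or mean
aggregation, and a post-aggregation multiplier.  The shipped defaults
follow the published instrument manuals (TAS-20 keys with items 4, 5,
10, 18, 19 reversed; DASS-21 subscale sums doubled to the 42-item
metric; MAIA-2 subscales as item means).  Two instrument ambiguities are
left configurable rather than hard-coded: the DASS-21 per-item range and
×2 convention, and the PANAS-SF layout (the 10-item short form scores
5 + 5 items summed 5–25, while some reports print subscale ranges near
10–50; the generator's subscale bounds and the item-level map are
therefore independent).  All scoring functions take the map as an
argument, so no analysis silently depends on the defaults; the test
suite always passes explicit maps.

TAS-20 totals classify as absence (≤ 51), possible (52–60) or presence
(≥ 61) of alexithymia.  `generate_item_level()` inverts scoring —
distributing subscale targets over items deterministically and
un-reversing keyed items — so scoring can be verified by exact round
trips.

## Diagnostics

`describe()` reports the bias-corrected skewness G1 and excess kurtosis
G2 by default (`type = "spss"`), the convention under which a balanced
binary variable at n = 230 shows kurtosis ≈ −2.0; raw moment ratios are
available via `type = "moment"`.  Normality is screened with the ±2
rule of thumb on both statistics — deliberately not a hypothesis test,
which at these sample sizes rejects trivially small departures.
Zero-variance columns are flagged, not fatal.

VIFs come from auxiliary regressions (VIF_j = 1/(1−R²_j)), which stay
defined (→ ∞) under perfect collinearity; a test cross-checks them
against the inverse-correlation-matrix diagonal to 1e−8 on full-rank
inputs.  Pairs with |r| ≥ 0.8 and VIFs ≥ 10 are flagged.  Residual
normality and homoscedasticity are reported numerically (residual shape
statistics and a Breusch–Pagan test) instead of probability and scatter
plots.

## Backward stepwise regression

Descriptions of backward selection often mix "improves R²" with
"minimizes AIC"; R² cannot drive backward elimination (it never
improves when a predictor is removed), so the single criterion here is
AIC decrease: at each step remove the predictor whose deletion lowers
the Gaussian AIC the most, stop when none does.  The AIC convention is
the standard Gaussian log-likelihood count (coefficients + intercept +
error variance), so traces are comparable across steps.  The classic
significance-to-stay rule (`criterion = "p"`, default threshold 0.10)
is provided as an alternative mode.  Every elimination step is recorded
(variable, AIC before/after), and the suite verifies each accepted step
against an exhaustive single-removal scan implemented independently in
the tests.

Power analytics use the noncentral F distribution with noncentrality
λ = f²·N — the total-sample convention used by standard power software;
the off-by-one alternative λ = f²·(v+u+1) does not reproduce the
familiar planning numbers (146 participants for u = 17, f² = 0.15,
power 0.80; power 0.97 at N = 230).  `required_n()` scans n upward,
which is exact and fast at these scales.

## Mediation

`mediate()` implements simple mediation — model-4 semantics: a from
`m ~ x`, b and c′ from `y ~ x + m`, c from `y ~ x` — with a percentile
case-resampling bootstrap CI for a·b.  Percentile is the default and
BCa is available, since macro defaults have differed across versions;
the package's calibration claims are about coverage, which the
acceptance suite measures directly (nominal 95% CIs cover a planted
indirect effect at rate 92–97% at n = 230 with 1,000 resamples, and
falsely exclude zero under an a ≠ 0, b = 0 null at most 7.5% of the
time — the percentile bootstrap's known mild anti-conservatism under
that null is why the band is not 5%).

The verdict logic is the conventional one: *none* if the CI covers
zero; otherwise *partial* if c′ remains significant and *full* if it
does not.  The identity c = c′ + a·b holds exactly for OLS on a fixed
sample and is asserted in the tests.  The bootstrap re-estimates a and
b with closed-form OLS on resample matrices (vectorized over all
resamples), which is what makes thousand-replicate calibration studies
affordable; the reported path table still comes from `lm()` fits.
`mediation_suite()` runs the standard quartet — interoceptive emotional
awareness and attention regulation as predictors × self-as-context and
AAQ-II as mediators — against the TAS total.

One caution encoded in the tests: when the mediator noise is small
relative to the a path, x and m become near-collinear and the b path is
poorly identified at any realistic n; calibration configurations keep
var(e_m) comparable to var(a·x).

## The deep network

The reference architecture is 17 × 30 × 30 × 30 × out with tanh units
in every layer, out = 3 for the joint subscale network and 1 for the
single-subscale networks.  Training is online backpropagation (per-row
updates in a seeded shuffled order) with momentum 0.1 and weight decay
1e−4; a full-batch mode is available.  Published settings for this kind
of network state two learning rates (0.001 and 0.05); the default here
is 0.05, with 0.001 one argument away.  Epochs default to 600 with the
retained weights chosen by minimum held-out error inside the 500–600
window — an overfitting guard that also resolves the fact that the
exact stopping epoch in such studies "varies between networks".

Because z-scored targets exceed tanh's codomain, targets are affinely
mapped to [−0.9, 0.9] by train-split min/max (the 0.9 margin keeps
gradients alive at the extremes); the map is stored with the network and
inverted for reporting, so estimates come back in raw outcome units.
Weights initialize uniformly on ±1/√fan-in from the network seed; the
split, initialization and visit order all derive from that one seed, so
training is bit-reproducible.  Divergence (non-finite error) aborts with
advice to lower the learning rate.  Gradients are verified against
central finite differences to 1e−5 on a micro-network, and the compiled
forward pass against a hand-written tanh cascade.

`validate_estimates()` regresses each actual outcome on the network's
estimate of it (Enter method), reporting adjusted R², F and
standardized β — the accuracy convention for network estimates of
questionnaire outcomes.  On data with planted group-specific slopes,
the network's validation R² exceeds the backward-stepwise linear R²
(typically ~0.8 vs ~0.3–0.4 in the shipped study configuration), the
qualitative signature of nonlinearity that motivates the design.

## Subgroup discovery and profiling

Clustering operates on the upper (third) hidden layer's activations —
the deepest representation, where the network has abstracted
predictor–outcome patterns.  Descriptions of this procedure sometimes
also mention clustering z scores of the raw variables; activations are
the default here, with `cluster_on = "z_scores"` available.

Stage one is Ward agglomeration under squared Euclidean distances
(`hclust` ward.D on squared distances; reported heights are converted
to within-cluster-SS increments and verified against a brute-force
O(N³) Ward in the tests).  The number of clusters is selected at the
largest relative jump between successive merge heights — an automated
stand-in for reading the dendrogram and agglomeration schedule by eye —
bounded above (default 6) and overridable.  Degenerate schedules (all
heights zero) collapse to k = 1 with a warning.

Stage two is Lloyd's K-means started exactly at the Ward centroids with
no random restarts, so the refinement is deterministic given the tree.
If a cluster empties mid-iteration its centroid is re-seeded at the
point farthest from it and the event logged.  The refinement can only
lower the within-cluster SS relative to the Ward cut (asserted in the
tests, along with agreement with `stats::kmeans` Lloyd on non-degenerate
inputs).

Profiles compare each group against all other groups combined on the
original variable scales: d = (mean_g − mean_rest)/√((SD_g² +
SD_rest²)/2).  The two-sample pooled-SD form is used; group-size
weighting is a defensible alternative but the unweighted form matches
the convention of the reports this pipeline mirrors.  Binary gender uses
an odds ratio converted by Chinn's rule d = ln(OR)/1.81 (with a Haldane
0.5 correction for empty cells); a literal OR/1.81 mode exists only for
auditing reports that applied the rule verbatim.  Flags follow Cohen's
bands — |d| ≥ 0.5 salient (medium/large), |d| ≥ 0.35 reported as small,
anything below suppressed (rendered `--`).

## Problem sizes in the validation suite

The shipped studies run at the design's natural scale: cohorts of
n = 230; 10 training seeds for the network-advantage and
subgroup-recovery studies; 1,000 simulated datasets with 1,000
bootstrap resamples each for mediation calibration; 200 random
instances (≤ 8 predictors) for stepwise-oracle equivalence; 20,000
replicates for the Monte-Carlo power cross-check.  These sizes give
stable pass/fail behavior (binomial/Monte-Carlo error well inside the
asserted bands) while keeping the whole suite in the minutes range on
one CPU.

## Known limitations

* The generator's Gaussian-then-clip marginals reproduce bounded Likert
  summaries but not item-level response processes; reliability and
  factor-structure questions are out of scope.
* The elbow rule is a heuristic; when cluster separation is weak it can
  pick k conservatively (the `k` override and the schedule are exposed
  for exactly that reason).
* Effect-size profiles treat groups as fixed partitions; no uncertainty
  is attached to d values, matching reporting practice but understating
  variability for small groups (groups under 2 members yield NA with a
  warning).
* Network training is full-precision, single-threaded and deliberately
  plain (no adaptive optimizers, no stratified splits), matching the
  simulator lineage of this design rather than modern deep-learning
  practice.
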