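---
title: "The McIA model and its analysis pipeline: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The McIA model and its analysis pipeline: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcia)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the experiment design it emulates, the
tunable parameters, the numerical choices, and the limits of what the
synthetic-data tests can show about real data.

## The task and the stimulus design

Observers categorize a gray-scale test face as belonging to one of two
families, each defined by a patriarch target face. A test face's top and
bottom halves are morphed independently: a morph is the pixelwise linear
combination `w*A + (1-w)*B` of the two targets (`morph_arrays()`), and the
proportion of the own-family target — the *morph level*, carried
everywhere in this package as a percent in [50, 100], never rounded —
controls the evidence strength of that half.

Evidence strengths are calibrated per participant, per half (top/bottom),
and per family. A 2-up-1-down staircase (5.6-point steps, bounds 50–100,
start 94, 18 trials) finds the *medium* level; the *weak* level is midway
between medium and the fully ambiguous 50% morph, and the *strong* level
is two-thirds of the way from medium to the 100% target:

```{r}
derive_levels(82)
```

`enumerate_test_faces()` builds the 56-face test set — 12 half faces, 18
same-family whole faces in each of two formats (*together*: normal
configuration; *split*: halves offset horizontally), and 4 *opposite*
faces (medium evidence for one family over weak evidence for the other)
in each format. `build_block()` arranges them into a 68-trial block (the
equal-strength w/w, m/m, s/s wholes appear twice) with one of nine random
screen positions per trial. Screen position and the split offset are
carried as labels only; neither has a model role. Analyses collapse
family and top/bottom location into 17 conditions: half w/m/s, whole
ww–ss by format, and the opposite cell `wom` by format.

## The McIA model

A decision is a random walk between absorbing thresholds at ±θ, starting
midway. Each step samples an evidence source: the automatically
integrated whole face with probability α, otherwise either half alone
(probability (1−α)/2 each). The whole-face step probability is the
odds-product (Bayes-optimal) combination of the half step probabilities
δ; a half whose family opposes the correct response contributes 1−δ.
Because the source is redrawn independently at every step, the walk is a
simple random walk at the marginal step probability
`alpha * combine_optimal(d_t, d_b) + (1 - alpha)/2 * (d_t + d_b)` — we
therefore compute that marginal once rather than simulating source
switches (exact distributional equivalence). Choice probability and the
unconditional expected step count then have gambler's-ruin closed forms
(`walk_choice_probability()`, `walk_expected_steps()`), evaluated with
real-valued exponents so non-integer thresholds are admissible; the
symmetric p = 0.5 limit (θ²) is used within 1e-7 of 0.5 to avoid
cancellation. Monte-Carlo equivalence with `simulate_walks()` is asserted
in the tests at integer θ only, because lattice walks absorb at
ceiling(θ).

The eight parameters (`mcia_params()`, defaulting to the published
best-fitting values):

| parameter | default | units | role |
|---|---|---|---|
| θ | 6.76 | steps | response threshold (distance from start to either boundary) |
| α | .30 | probability | whole-face (optimal) sampling for together faces |
| δ_weak, δ_medium, δ_strong | .54, .56, .64 | probability | step toward correct per half-face strength |
| τ | 359 | ms | non-decision time |
| k | 20 | ms/step | step time |
| h | 1.24 | — | half-face step-time multiplier |

RT = τ + kN for whole faces and τ + hkN for half faces (half faces were
empirically much slower; h absorbs the extra per-step cost of comparing a
half face to whole targets). Expected steps are unconditional over correct
and error responses: condition mean RTs are reported without response
conditioning, so the fit uses the matching quantity.

Model variants differ only in how α (and the split-face rates) are set:
`full` (α free for together, 0 for split), `alpha_one` and `alpha_zero`
(optimal or averaging everywhere), `alpha_split_free` (separate free α per
format), and `rate_attenuation` (α = 1 everywhere, split δs multiplied by
a free γ in [0, 1]).

The model's *deviation score* prediction for a whole or opposite face is
its choice probability minus the choice probability of its stronger half
alone (the half with the larger effective δ; for `wom`, the medium half by
definition of the correct response). Under `alpha_one` every same-family
whole-face deviation is non-negative (the odds product dominates either
input above .5) and under `alpha_zero` every deviation is non-positive
(an average cannot exceed its larger term) — the sign dichotomy that makes
the hybrid necessary. The `wom` cells are the exception worth noting:
optimal combination of medium evidence with *opposing* weak evidence
rationally lands below the medium half alone, so `wom` deviations are
negative even under `alpha_one`; the sign properties are therefore stated
over the 12 same-family whole-face cells.

## Staircase calibration and the synthetic observer

The 2-up-1-down rule converges where P(correct)² = 1/2, i.e. ~70.7%
correct, *provided* the 5.6-point step is small relative to the width of
the observer's psychometric function. The synthetic observer
(`psychometric_observer()`) is a logistic in morph percent anchored at
exactly chance for the 50% morph — the simplest monotone family with that
anchor — with its 75%-correct midpoint and slope configurable and a small
lapse rate capping asymptotic accuracy; the logistic center is solved
numerically so both anchors hold at once. The default slope of 0.08 per
morph percent spreads the transition over several tens of morph points,
which is what staircase-calibrated face-morph discrimination looks like
(medium levels land in the 70s–80s) and which keeps the staircase in the
regime where the convergence theorem applies; steep observers (width
comparable to the step) converge measurably below the nominal 70.7%, a
standard transformed-staircase caveat rather than a bug.
`converged_accuracy()` runs a 20,000-trial staircase by default, averages
the level over the post-burn-in half (the mean stabilizes to ~0.25
accuracy points across seeds at that length), and evaluates the observer
there. The consecutive-correct counter resets both after a decrement and
after any error (the standard transformed-staircase convention), and the
5.6-point step is applied before clamping to [50, 100]. The calibration
protocol's four staircases (top/bottom × family) are simulated
independently; the interleaved whole-face filler trials of the original
protocol affect nothing downstream and are omitted.

## The behavioral pipeline

`filter_trials()` removes trials with confidence 50, RT < 150 ms, or
RT > 5000 ms — strict bounds, so 150 and 5000 themselves survive.
Accuracy is coded against `correct_family()` (the shared family, or the
medium half's family for opposite faces). Deviation scores subtract, per
participant, the mean accuracy of the *empirically* stronger half face
(computed after filtering, for consistency with every other summary);
ties are broken by strength label (s > m > w), then toward the top half.
`summarize_conditions()` averages within participant first and reports
between-subject SEMs (sd of participant means / √n), flagging cells with
fewer than two participants. `strength_difference_table()` codes whole
faces by |strength difference| (equal −1, one step 0, two steps +1) and
`median_split()` classifies each trial as fast or slow at its own
participant's median RT (ties to slow).

## Fitting

`wsse_objective()` standardizes each of the 48 cells (17 accuracies, 17
mean RTs, 14 deviation scores) by its between-subject SEM, squares, and
sums. Minimization is Nelder–Mead on transformed coordinates: log for θ,
k, h; logit for α, α_split, γ; a bounded logit keeping each δ in
(.5, .999) — a δ below .5 would mean a half face carrying evidence for
the wrong family, which the calibration design excludes; identity with a
floor at 0 for τ. No ordering constraint is imposed on the δs; the
ordering is reported, not enforced. The search runs 25 jittered restarts
by default (sd 0.5 on the transformed scale), then polishes by re-seeding
the simplex around the incumbent at shrinking scales — repeated restarts
grind through the shallow valleys where a single simplex run stalls — and
a final run at reltol 1e-8 supplies the convergence flag. Restarts that
hit a non-finite objective are discarded and counted. θ and k trade off
(accuracy constrains roughly δ^θ while mean RT constrains kθ²), so θ is
the least identified parameter in recovery studies; α and the δ ordering
recover reliably at the experiment's scale.

## The synthetic-data generator

`simulate_experiment()` is the package's stand-in for the unpublished
participant data and the Monte-Carlo oracle for the closed forms. Per
participant it runs the four calibration staircases, enumerates and
shuffles blocks, and generates every trial from the McIA walk itself at
that participant's parameters. Defaults are the experiment's stated
conditions: 19 participants, 4 blocks of 68 trials, generating parameters
at the published values. Where the experiment stated no value the
defaults are fixed once: between-participant jitter (lognormal on θ and
k, logit-normal on α and the δs, scale 0.1) sized to give realistic
between-subject SEMs; contamination totalling 13% — the reported removal
fraction — split as 2.6% confidence-50 trials (near the reported
per-format rates) and 5.2% each fast guesses (uniform on (0, 150) ms) and
slow outliers (uniform on (5000, 8000) ms), planted by overwriting
generated trials and recorded in a ground-truth label. Confidence ratings
are a placeholder (monotone in step count over {60..100} with categorical
noise): the model does not define confidence, and the value exists so the
confidence filter and the I/O schema are exercised. RTs are real-valued
milliseconds (no screen-refresh quantization).

Two deliberate realism notes. First, the walk's own RT tail crosses 5 s
occasionally (~0.3% of trials at the default parameters), so even a
zero-contamination simulation loses a few trials to the slow filter —
exactly as real data would. Second, the empirical deviation reference is
the *maximum* of two noisy half-face accuracies (~16 trials per half
condition), which biases simulated deviation scores slightly negative
relative to the model's own predictions; the same selection bias operates
in real data. A condition at ceiling for every simulated participant has
a zero between-subject SEM, which cannot weight a least-squares cell;
`make_observed_summary()` floors such SEMs to the smallest nonzero SEM of
the same measure so summaries are always fittable.

What passing these tests does and does not show: the generator reproduces
the design's structure, the model's choice/RT laws, and the filters'
failure modes, so it validates the pipeline's arithmetic and the model's
internal consistency end to end. It does not emulate sequential effects,
learning or fatigue across blocks, real confidence behavior, stimulus
idiosyncrasies (individual faces), or eye-movement strategies — agreement
on synthetic data is necessary, not sufficient, for claims about real
observers.

## Problem sizes used in the shipped checks

The test suite cross-validates the closed forms against 100,000
Monte-Carlo walks per cell over p ∈ {.52, .6, .7, .8, .9} × θ ∈ {1,…,8}
(3-standard-error agreement), runs staircase convergence at 20,000 trials,
and performs 20 seeded parameter-recovery replications at the full
19 × 4 × 68 experiment scale with 6-restart fits, asserting that α lands
within ±0.15 of truth and the δ ordering is recovered in at least 80% of
replications (the θ error distribution is reported alongside).

## Known limitations

* Only mean RTs are modelled; full RT distributions and conditional
  (correct-only) RTs are out of scope, matching the fitting target.
* The `wom` modelling convention (opposing evidence as 1−δ) is an
  interpretation; alternatives (e.g. a free opposite-face rate) were not
  explored.
* Headline fitted quantities from the original dataset (best-fit wSSE
  values, Table-style coefficients) depend on unpublished raw data and
  are not reproducible here; the package targets the worked examples and
  property-level behavior instead.
* Real image processing (warping, cropping, grating backgrounds) is out
  of scope; `morph_arrays()` retains only the numeric morph operation.
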