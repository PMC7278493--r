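---
title: "Decoding estrus behavior from tracking data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding estrus behavior from tracking data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrusHMM)
```

## The problem

Estrus in goats announces itself behaviorally: a receptive female approaches
the male's enclosure and stands near it, often for long stretches. If those
proceptive behaviors can be read automatically from an overhead camera, estrus
detection no longer requires continuous human observation. The raw material is
modest — a marker on the goat's back tracked at one position fix per 0.5 s, so
a 10-minute recording gives K = 1200 frames of pen coordinates — and a trained
observer's frame-by-frame scoring of three ethogram states:

* state 0 — behavior besides approaching and standing,
* state 1 — approaching the male,
* state 2 — standing near the male.

By convention the male paddock is adjacent to the small-x side of the pen, so
states 1 and 2 live at small x. Each frame contributes the observable
3-vector `z_k = (x(k), y(k), L(k))`, where the step length
`L(k) = sqrt((x(k+1)-x(k))^2 + (y(k+1)-y(k))^2)` measures per-frame
displacement. `L(K)` has no successor frame; we carry the last defined value
forward (`L(K) = L(K-1)`) so that every frame has a complete observation and
the per-animal frame count is preserved. `stepLengths(..., last = "drop")`
switches to dropping the final frame instead.

## The model

Behavior is modeled as a first-order Markov chain over the three states with
transition matrix `T` (`p_ij = p(s_{k+1} = j | s_k = i)`), and the observables
as state-conditional densities `p(z_k | s_k)`, each a mixture of
diagonal-covariance 3-D Gaussians. Training is fully supervised — no
Baum–Welch — because observer labels exist for every training frame:

* `T` is estimated by counting label transitions, pooled over all training
  animals (estrus and non-estrus together, since non-estrus animals also
  inform the model of states it must recognize everywhere).
* `p(z | s)` is fitted by EM to the frames labeled `s`, with the component
  number chosen by AIC over a grid (default 1–15).
* The initial distribution `pi` is the empirical distribution of first-frame
  training labels.

Decoding computes the smoothed posterior `p(s_k | Z_K)` by forward filtering
(one-step prediction then measurement update) followed by the backward
recursion

```
p(s_k | Z_K) = p(s_k | Z_k) * sum_{s_{k+1}} p(s_{k+1} | Z_K) p(s_{k+1} | s_k) / p(s_{k+1} | Z_k)
```

and assigns each frame its marginal MAP state. Per-frame marginal decoding
(not Viterbi joint decoding) is deliberate: the quantity scored downstream is
frame-wise concordance, which the marginal argmax optimizes.

## Numerical choices

* **Emission weighting in log-space.** The forward update applies emission
  terms as `exp(logdens - max)` with per-frame renormalization, so recordings
  of any length and densities of any magnitude (tiny variances produce
  per-frame densities around 1e9) cannot underflow. A property test verifies
  that an affine change of coordinate units, which scales every state's
  density by the same factor at every frame, leaves posteriors unchanged.
* **Zero guards.** Unseen transition rows become uniform; remaining zero
  cells (and `pi`) are floored at 1e-10 and renormalized, keeping
  log-probabilities finite without materially moving counted estimates. In
  the backward ratio, terms with zero predictive probability contribute zero.
* **EM.** Deterministic seeded k-means initialization, at most 200
  iterations, relative log-likelihood tolerance 1e-8, single restart.
  Non-convergence returns the best iterate with a warning rather than
  failing: near-converged mixtures are routinely adequate for decoding.
* **Variance floor.** Every mixture variance is floored at 1e-6 squared
  length-units, which keeps densities finite for degenerate (e.g. constant
  coordinate) training data.
* **AIC parameter count.** With 3-D observations each component carries 3
  means and 3 variances, plus m − 1 free weights: `p = 7m − 1`. AIC is
  `−2 loglik + 2p`. Ties in the AIC grid go to the smaller m.
* **Tie-breaks.** MAP decoding breaks posterior ties toward the smaller state
  index, so ties resolve away from asserting estrus behavior.
* **Exactness oracle.** `bruteForcePosterior()` enumerates all `3^K` paths
  (refusing K > 10) and is compared to the forward-backward smoother in the
  tests; agreement is at machine precision, far inside the 1e-8 gate.

One caveat worth knowing: AIC for nested mixtures has a small but real
overselection probability — on a true single Gaussian at n = 5000 a spurious
second component clears the 2·7 penalty in a nontrivial fraction of datasets.
Validation checks therefore assert the modal AIC choice across several
independently generated datasets rather than a single draw.

## Frame-wise comparators

Three classifiers predict the state of each frame from `z_k` alone, ignoring
temporal structure — exactly the contrast the HMM is meant to win on:

* **Random forest** (`randomForest`), 1 feature tried per split, 500 trees.
* **RBF-kernel SVM** (`kernlab::ksvm`), kernel width and cost grid-searched
  (defaults `10^-2..10^5` and `10^-1..10^3`) by k-fold cross-validation with
  k from Sturges' formula `floor(1 + log2(n))` — 14 folds at n = 9600. The
  selected pair is recorded per run rather than hard-coded, since grid search
  outcomes are data-dependent.
* **Neural network** (`nnet`), one hidden layer of 10 units; inputs are
  standardized (stored and re-applied at prediction) to help the optimizer.

A property test confirms frame independence: permuting other frames never
changes a frame's prediction.

## Scoring

Concordance is counted frame-by-frame per behavior (1 and 2 separately) with
a ±1-frame tolerance window: an observed-behavior frame is a TP if the
prediction shows the behavior within the window, else an FN; a predicted
frame with no observed behavior in its window is an FP. Windows truncate at
recording edges; no event segmentation or one-to-one matching is performed.
Then `PC = 100·TP/(TP+FN+FP)`, with FP and FN shares reported on the same
denominator so the three sum to 100. When a behavior occurs in neither
sequence, PC is 100 (the estimate agrees that the behavior is absent); when
it is only predicted, PC is 0 with an FP share of 100.

Behavioral time budgets (percent of frames in states 1 and 2) are compared
between observation and each method by a paired two-sided t-test across
animals — paired because each animal yields an (observation, method) pair; a
Welch two-sample variant is available via `paired = FALSE`. Identical budget
vectors have zero-variance differences and are flagged degenerate instead of
erroring.

## The synthetic cohort generator

No tracking data accompany the study, so the generator supplies cohorts with
the same statistical skeleton: 16 animals (8 estrus, 8 non-estrus), 1200
frames each, three labeled states. One `stateProfile()` is shared by all
animals — where a state happens in the pen is a property of the state, not of
the animal — while the groups differ in their transition matrices: the
default estrus chain dwells mostly in states 1–2 (stationary occupancy
concentrated near the male side), the non-estrus chain mostly in state 0.
Both defaults are strongly diagonal (self-transitions ≥ 0.9), reflecting
behavioral persistence at 0.5 s resolution. The pen is the unit square by
default, since the tracker's units are unknown; a 2.5 m physical pen is one
config field away.

Positions are generated in one of two modes:

* **walk** (default): an AR(1)-style walk pulled toward the active state's
  position kernel with state-specific noise, so step length carries state
  information (approaching = large steps toward small x, standing = tiny
  steps at the male fence) and positions are autocorrelated, as in real
  tracks. This deliberately violates the HMM's iid-emission assumption the
  way real data do.
* **gaussian**: iid per-frame draws from the state kernel, matching the
  model's own emission assumption exactly — used where tests need
  oracle-sharp recovery.

Labels equal the generating states, optionally flipped at a configurable
label-noise rate. Animal i is simulated from `cohort seed + i`, so any single
animal regenerates independently. The movement parameters are chosen for
testability, not biological fidelity: passing recovery tests demonstrates the
estimator is consistent with its own generative assumptions, not that real
goats satisfy them. Real tracking data add inter-animal variability,
observer disagreement, marker dropouts and non-Gaussian step-length
distributions that the generator does not emulate.

## Validation design and problem sizes

The acceptance-style checks run at the study's scale: cohorts of 16 × 1200
frames with an 8-animal training split; AIC recovery at n = 5000 per dataset
with 10-sigma component separation; t-test calibration over 1000 simulated
null cohorts of 8 animals. For parameter recovery the two groups share a
single true transition matrix — with group-specific chains the pooled
supervised estimate converges to an occupancy-weighted blend and "distance to
truth" is ill-defined — and use the `gaussian` mode with
`separatedStateProfile()`, under which held-out decoding should be
essentially perfect. Unit tests reuse the same machinery at reduced sizes
(300–500 frames, 6 animals) to stay fast; the long-chain checks (transition
recovery, stationary occupancy) use single 1e5-frame chains.

## Known limitations

* Supervised training only; no unsupervised re-estimation (Baum–Welch) and
  no covariate-dependent or continuous-time transitions.
* Step length is modeled inside a Gaussian mixture although it is a
  non-negative quantity; a positive-support distribution (gamma, Weibull)
  would be more faithful and is a natural extension.
* The concordance metric is frame-based; it says nothing about event counts
  or durations.
* Timings reported by `runExperiment()` are informational only and depend on
  hardware and backend libraries.
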