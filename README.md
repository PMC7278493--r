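# estrusHMM

Estrus in female goats is visible in behavior: a receptive female approaches
the male's paddock and stands near it. **estrusHMM** estimates those
proceptive behaviors automatically from overhead video-tracking coordinates,
replacing continuous human observation with a statistical decoder, and is
aimed at researchers in computational ethology and precision livestock
monitoring who have frame-indexed position tracks plus observer-scored
training recordings.

## The model

Each frame k (one per 0.5 s; a 10-min recording is K = 1200 frames) carries
an observable 3-vector

    z_k = (x(k), y(k), L(k)),      L(k) = sqrt((x(k+1)-x(k))² + (y(k+1)-y(k))²)

and a latent behavioral state s_k ∈ {0, 1, 2} (0 = other behavior,
1 = approaching the male, 2 = standing near the male; the male paddock sits
at the small-x side of the pen). The states follow a Markov chain with
transition matrix T; observations follow state-conditional
diagonal-covariance Gaussian mixtures p(z_k | s_k), with the component
number per state selected by AIC. Training is supervised: T is counted from
observer label sequences, the mixtures are EM-fitted to labeled frames.
Decoding computes the smoothed posterior by forward filtering,

    p(s_k | Z_{k-1}) = Σ_{s_{k-1}} p(s_k | s_{k-1}) p(s_{k-1} | Z_{k-1})
    p(s_k | Z_k)     ∝ p(z_k | s_k) p(s_k | Z_{k-1})

then the backward recursion

    p(s_k | Z_K) = p(s_k | Z_k) Σ_{s_{k+1}} p(s_{k+1} | Z_K) p(s_{k+1} | s_k) / p(s_{k+1} | Z_k)

and assigns each frame s_k = argmax p(s_k | Z_K). Frame-wise baselines
(random forest with mtry 1, grid-searched RBF-SVM with Sturges-formula CV
folds, a 10-unit single-hidden-layer neural network) predict from z_k alone.
Agreement with the observer is scored per behavior by percentage concordance
with a ±1-frame tolerance window,

    PC = 100 · TP / (TP + FN + FP),

and behavioral time budgets are compared by paired t-tests. A synthetic
cohort generator (16 animals, 8 estrus / 8 non-estrus, 1200 frames each)
reproduces the statistical structure of the tracking data so the whole
pipeline is testable end to end. See the methods vignette
(`vignettes/estrus-hmm-methods.Rmd`) for assumptions and numerical choices.

## Worked example

```r
library(estrusHMM)

cohort <- simulateCohort(cohortConfig(seed = 11))
res <- runExperiment(
  experimentConfig(cohort, methods = c("hmm", "rf"), m_grid = 1:5, seed = 11))

res$models$hmm
#> Supervised 3-state estrus-behavior HMM
#> Markov transition matrix (rows: from-state 0..2):
#>     to
#> from      0      1      2
#>    0 0.9661 0.0262 0.0077
#>    1 0.0607 0.8846 0.0547
#>    2 0.0098 0.0164 0.9738
#> initial distribution pi: 0.25 0.375 0.375
#> state 0 emission: m = 5 (AIC -32965.0), n = 3891
#> state 1 emission: m = 5 (AIC -8872.1), n = 1500
#> state 2 emission: m = 5 (AIC -81154.9), n = 4209

head(subset(res$concordance, !is_training & method == "hmm"), 4)
#>    method animal_id    behavior  TP FN FP       PC     FP_pct    FN_pct
#> 9     hmm estrus_05 approaching 318  1 71 81.53846 18.2051282 0.2564103
#> 10    hmm estrus_05    standing 657 12  0 98.20628  0.0000000 1.7937220
#> 11    hmm estrus_06 approaching 204 11 66 72.59786 23.4875445 3.9145907
#> 12    hmm estrus_06    standing 611 16  5 96.67722  0.7911392 2.5316456
```

The fitted transition matrix is strongly diagonal — behaviors persist across
0.5-s frames — and the counted rows sit close to the generator's truth
(self-transitions 0.95/0.90/0.98). For each held-out animal and behavior the
table gives windowed TP/FN/FP counts and their percentage shares: e.g. for
`estrus_05`, 98.2% of standing-behavior frames are concordant with the
observer within ±1 frame, and the approaching errors are dominated by false
positives (18.2%), the behavior's transitions being brief and position-
ambiguous. `res$budgets` and `res$ttests` compare time spent per behavior
between observation and each method, and `res$timings` reports wall-clock
seconds per method (informational).

A thin CLI over the same functions is included:

```sh
Rscript inst/scripts/estrus-pipeline.R simulate --out cohort/ --seed 1
Rscript inst/scripts/estrus-pipeline.R run --cohort cohort/manifest.csv --out results/
```

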