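---
title: "Methods: multiscale-entropy EEG biomarkers for dementia severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale-entropy EEG biomarkers for dementia severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmse)
```

## The problem

Progressive dementia is accompanied by a loss of "complexity" in resting
EEG: the signal becomes more regular at fast time scales while relatively
preserving or even gaining irregularity at slow scales. This package
implements a complete analysis chain for studying that phenomenon across
severity groups (healthy controls `HC` and three dementia severity levels
`AD1` < `AD2` < `AD3`):

1. **Feature extraction** — multiscale entropy (MSE) per channel: sample
   entropy of coarse-grained versions of the signal at scale factors
   $\tau = 1..20$, giving $19 \times 20 = 380$ features per 19-channel
   session.
2. **Classification** — pairwise group contrasts with natively
   implemented L1 (LASSO) and elastic-net penalized logistic regression
   under leave-one-subject-out cross-validation (LOSO), with the penalty
   weight chosen by nested subject-grouped cross-validation.
3. **Biomarker maps** — per-feature selection frequencies across LOSO
   folds, aggregated into five scale bins per channel (maximum within
   bin) on the 10–20 montage.
4. **Symptom association** — canonical correlation analysis (CCA)
   between the entropy features and the 12 neuropsychiatric-inventory
   (NPI) symptom scores, summarized by structure coefficients.

Because no clinical recordings ship with the package, a seeded synthetic
cohort generator reproduces the statistical geometry the analysis
assumes, so that every stage is testable end to end.

## Multiscale entropy

Coarse-graining at scale $\tau$ replaces the series by means of
consecutive non-overlapping windows of length $\tau$ (trailing remainder
dropped). Sample entropy of the coarse series $y_1..y_M$ with template
length $m$ and tolerance $r$ is

$$\mathrm{SampEn} = -\ln \frac{N_{m+1}}{N_m},$$

where $N_m$ counts ordered pairs $(k < l)$ of $m$-length templates whose
Chebyshev distance is strictly below $r$, and $N_{m+1}$ counts the same
for $(m{+}1)$-length templates. Numerical conventions, chosen where the
field literature is ambiguous:

* **Template index range.** Both counts run over start indices
  $1..M-m$, so $N_{m+1}/N_m$ is a proper conditional probability and a
  constant series yields exactly 0.
* **Tolerance.** $r = 0.15 \times \mathrm{SD}$ of the *original*
  (scale-1) series, computed once per channel and reused at every scale
  (the Costa convention). This makes the whole curve invariant under
  affine rescaling of the input, which the tests assert.
* **Distance and inequality.** Chebyshev distance with strict `< r`
  matching, the Richman–Moorman standard.
* **Undefined scales.** If either count is zero (possible for short or
  pathological coarse series) the scale is flagged `NA` and recorded in
  `undefined_scales` instead of aborting a cohort run.
* **Detrending.** `extract_features()` removes a per-channel linear
  trend before the SD is computed; raw `mse_curve()` leaves the input
  untouched.

Defaults are $m = 2$, $r = 0.15$, scales $1..20$; with 10 s at 256 Hz
the scale-20 series still has 128 samples. Correctness is pinned by
three independent oracles: a naive $O(M^2)$ counter (agreement to
1e-12), the analytic white-noise limit
$-\ln\,\mathrm{erf}(r/2) \approx 2.47$ for unit-variance Gaussian noise
(within 2% at $M = 10^5$), and exact-zero entropy on constant series.

## Penalized logistic regression

The solver maximizes

$$\sum_i \left[ y_i \eta_i - \log(1 + e^{\eta_i}) \right]
  - \lambda \sum_j \left[ (1-\alpha)\beta_j^2 + \alpha|\beta_j| \right],
  \qquad \eta_i = \beta_0 + \beta^\top x_i,$$

by iteratively reweighted least squares with active-set coordinate
descent on each quadratic subproblem (C++), step-halving to keep the
exact objective monotone, and convergence declared on the subgradient
(KKT) residual of the exact problem. $\alpha = 1$ is the LASSO;
$\alpha = 0.7$ is the elastic-net default. The quadratic term is written
$(1-\alpha)\beta_j^2$ (the Zou–Hastie elastic-net reading); the
intercept is never penalized. The implementation is native, with three
independent oracles in the tests: `stats::glm` at $\lambda = 0$, a
term-by-term transcription of the objective, and `glmnet` under the
exact objective reparameterization.

Choices where the design was open:

* **Standardization.** Features are z-scored with training-fold
  statistics only; a shared $\lambda$ across 380 features is
  meaningless otherwise, and doing it per fold avoids information leak.
* **Penalty path.** $\lambda_{\max} = \max_j |\sum_i x_{ij}(y_i -
  \bar y)| / \alpha$ (the smallest penalty with an all-zero solution),
  50 log-spaced points down to $10^{-3}\lambda_{\max}$.
* **$\lambda^*$ criterion.** Minimum mean held-out binomial deviance
  over a subject-grouped inner CV (default 5-fold), not the 1-SE rule —
  the simplest defensible default, recorded in run metadata. Inner-CV
  fits use a looser KKT tolerance (1e-4) than final fits (1e-7): they
  only feed deviance estimates, and this keeps full runs inside
  practical time budgets.
* **No class re-weighting.** Imbalance is reported through AUC instead.
* **Unpenalized baseline.** `method = "lr"` fits $\lambda = 0$ under an
  iteration cap; with $p = 380 > n$ the classes are separable, the
  likelihood has no maximizer, and the fit deliberately reports
  `converged = FALSE` while reaching 100% training accuracy — the
  overfitting signature the regularized methods are compared against.

## Cross-validation design

LOSO folds hold out all sessions of one subject; standardization,
$\lambda$ selection and fitting see training rows only. Test metrics
(accuracy, sensitivity, specificity; positive class = the more severe
group) are computed on session-level predictions pooled across folds,
and AUC is the rank-based Mann–Whitney statistic on the pooled
probabilities — per-fold AUC would be undefined because a 3-session test
fold is usually single-class. Train accuracy is averaged across folds.

One behaviour of this design is worth knowing: on *signal-free* data
with small balanced cohorts, LOSO accuracy falls systematically *below*
chance (the anti-learning artifact). Holding out one subject makes the
opposite class the training majority, so a near-null model predicts
that majority for every held-out session — which is always wrong. The
null-cohort test asserts the absence of spurious skill (accuracy and
AUC do not exceed chance), not symmetric chance-level behaviour.

## Selection-frequency maps

A feature counts as selected in a fold when its fitted coefficient
exceeds 1e-8 in absolute value (coordinate descent produces exact
zeros; the threshold only guards float dust). "Replications" are the
LOSO folds, the only repetition loop in the design. Frequencies are
aggregated per channel into the five bins 1–4, 5–8, 9–12, 13–16, 17–20
by taking the **maximum** within each bin, and exported with schematic
2-D 10–20 coordinates (decorative only).

## Canonical correlation

CCA is solved by SVD of the whitened cross-covariance with
pseudo-inverse whitening: centered blocks are reduced by thin SVD,
singular values below a rank tolerance dropped, and the canonical
weights back-transformed. Unregularized whitening is deliberate: with
$p = 380$ features and fewer samples the centered feature block spans
the whole sample space and the leading canonical correlation is exactly
1 — the degenerate geometry the analysis is expected to report, which
regularized CCA would hide. Structure coefficients (correlation of each
original variable with its own block's canonical variate) are the
interpretable output in that regime; constant columns yield flagged
`NA`s. CCA is fitted on subject-averaged session features so one
feature row pairs with one symptom row (avoiding pseudo-replication of
identical NPI rows), and Y is centered but not rescaled (correlations
are scale-invariant).

A subtlety the tests respect: whenever $p + q > n - 1$ the two centered
subspaces must intersect, so the leading pairs have correlation exactly
1 and are arbitrary up to rotation — *recovery* of a planted
association is only a meaningful test in a regime with $p + q < n - 1$,
which the recovery test enters by restricting to short-scale features.

## The synthetic cohort

The generator states a world and keeps it fixed:

* **Signal model.** Each channel is a standardized mixture
  $\sqrt{1-w}\,\text{white} + \sqrt{w}\,\text{pink}$ of white and
  spectrally shaped $1/f$ Gaussian noise. White noise loses sample
  entropy under coarse-graining (relative to the fixed scale-1
  tolerance) while $1/f$ noise does not, so a higher pink weight $w$
  lowers short-scale entropy and flattens the curve — the minimal model
  with the crossover geometry of the dementia-severity literature, with
  no physiological rhythms, artifacts or drowsiness.
* **Severity gradient.** Effect channels T5, T6, O1, O2 receive group
  weights 0.2 / 0.35 / 0.5 / 0.8 (HC / AD1 / AD2 / AD3); all other
  channels share the baseline 0.3. The gradient makes HC vs AD3 easily
  separable and HC vs AD1 hard, mirroring the ordering of accuracies in
  the clinical literature, and is calibrated to orderings only, not
  magnitudes.
* **Crossover location.** The HC-vs-AD3 mean-difference MSE curve of
  this mixture changes sign at scale ≈ 4 (Monte-Carlo, 200 seeds);
  clinical curves cross nearer scale 8. The mixture reproduces the
  existence and direction of the crossover, not its exact scale; the
  frozen test asserts a single sign change in scales 3–5.
* **Subjects and symptoms.** Each subject's effect weight is jittered
  (SD 0.05, clipped to [0,1]) and doubles as the latent severity. NPI
  scores are `loadings × severity + N(0, 0.5²)` truncated at 0, with
  12×1 default loadings largest on apathy, dysphoria, anxiety,
  agitation and night-time disturbance. `noise_sd = 0.5` was chosen
  once so the strongest symptom–severity correlation is comfortably
  above 0.5; it was not tuned against test outcomes.
* **Determinism.** Every signal and score is a pure function of the
  spec seed via deterministic sub-seed derivation, so cohorts are
  byte-identical across runs.

What a green test establishes: the pipeline recovers planted effects of
this geometry. What it does not: performance numbers on clinical EEG
(artifacts, rhythms, volume conduction, inter-channel correlation are
all absent), which is why the headline clinical accuracies are not
acceptance targets.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(group_sizes = c(HC = 6, AD3 = 6), seed = 11)
cohort <- generate_cohort(spec)
features <- extract_feature_table(cohort$recordings)

cv <- run_loso(features, analysis_config(method = "lasso",
                                         contrast = c("HC", "AD3")))
performance_table(cv)
map <- bin_frequencies(selection_frequency(cv))

sa <- subject_average_features(features)
npi <- cohort$npi[match(sa$subject_id, cohort$npi$subject_id), ]
cca <- fit_cca(sa$X, as.matrix(npi[, NPI_SYMPTOMS]))
cca$correlations[1]   # 1: p = 380 features, 12 subjects
```

## Known limitations

* The EDF reader supports the common uniform-rate subset of EDF only
  (no annotations, no per-channel rates) and there is no EDF writer.
* Selection frequencies carry no formal error control; they are
  descriptive stability measures, not Meinshausen–Bühlmann bounds.
* The synthetic generator models neither spatial correlation between
  channels nor non-stationarity; classifier performance on it is
  optimistic relative to clinical data.
* With `method = "lr"` on separable data, coefficients grow without
  bound by design; predicted probabilities saturate and should not be
  interpreted.
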