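---
title: "Methods: design, synthetic data and models in oddpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, synthetic data and models in oddpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oddpred)
```

## The scientific problem

In the classic auditory oddball paradigm a frequent standard tone is
occasionally replaced by a rare deviant, and the brain's mismatch responses
(MMN, P3a) index how well the listener's auditory system has extracted the
*global rule* — "the most probable sound on any trial is the standard".
`oddpred` implements the full analysis chain for a modified oddball design
in which two deviant pitches additionally carry opposed *conditional
repetition rules*: one deviant is followed by an identical deviant with
probability 0.8 (repetition rule), the other with probability 0.2
(nonrepetition rule). The design dissociates conditional from global
stimulus probability: a second deviant violates the global rule but may
confirm the conditional rule, while a standard after a deviant confirms the
global rule but may violate the conditional one.

The package covers: constrained sequence generation, synthetic ERP and
behavioural data with known ground truth, epoch-level preprocessing and
averaging, temporal exploratory factor analysis (EFA), signal-detection
summaries, JZS Bayes factors with a fixed-n design analysis, and a
hierarchical lognormal power-law model for single-trial response times.

## Sequence generation

A block is assembled from *deviant events* — a first deviant optionally
followed by one identical deviant — separated by runs of standards. The
composition is exact by construction: with the defaults, 30 first deviants
per type per block, of which round(30 × 0.8) = 24 repetition-rule and
round(30 × 0.2) = 6 nonrepetition-rule events repeat, giving 345 standards
and 90 deviants in 435 trials, and over 20 blocks the familiar totals
(6900/1800/600 per type, 1080 vs 720, 480 conforming vs 120 violating per
rule).

Choices the design description leaves open, fixed here once:

* **Spacing.** At least `min_standards_between_events = 2` standards
  separate deviant events, and — a refinement beyond the minimal reading —
  the same margin is reserved *after the final event* of a block. Without
  it a block can end on a first deviant whose Position-2 stimulus never
  occurs, breaking the exact 480/120 arithmetic and making count tables
  seed-dependent.
* **Lead-in.** Blocks open with exactly five standards; these are excluded
  from the global standard so that the standard regularity can build up.
* **Behavioural task.** The six 220-trial blocks are not broken down in the
  source description; 175 standards + 15 first deviants per type + 12/3
  second deviants preserves the exact 0.8/0.2 probabilities with integer
  counts.
* **Placement.** Deviant events are shuffled and the remaining standards
  distributed over the inter-event gaps by a uniform random composition —
  deterministic under a seed, and every generated sequence is audited
  against the constraints (no nonidentical deviant adjacency, no triple
  deviants, spacing, lead-in).

## Synthetic ERP data

The ERP generator is a *stated world*, not a fit to data: each epoch is
`sum_f topography_f ⊗ loading_curve_f × score_f + noise`, with

* five Gaussian loading curves (unit peak, µV per unit score) at 105, 145,
  191, 246 and 289 ms (SD 25 ms), mimicking the latencies of N1, P2a, P2b,
  early and late P3a;
* topography weights 1 on the frontocentral ROI (FCz, FC1, FC2, Fz), 0.5 on
  other scalp channels and −0.3 on the mastoids (polarity inversion);
* condition mean scores set to published frontocentral peak-amplitude
  estimates for the seven averaging conditions (global standard, Position-1
  deviants, Position-2 deviants and standards by rule), so that with unit
  peak loading and unit ROI weight the factor-wise reconstructed ROI peak
  equals the score;
* between-participant score SDs equal to the global-standard standard
  errors scaled by √60;
* AR(1) temporal noise (φ = 0.3, single-epoch SD 10 µV) mixed through an
  exchangeable channel correlation (ρ = 0.3). Condition averages carry this
  noise scaled by 1/√n, which is distributionally identical to averaging
  per-epoch noise.

What the generator does **not** emulate: continuous raw EEG, ocular or
muscle artefacts, latency jitter, inter-channel topography differences per
factor beyond the three-level weighting, or single-trial score variability
within a participant. A green recovery test therefore establishes the
correctness of the estimators under the factor model, not their robustness
to violations of it.

## Epoch pipeline

Epochs span −100…700 ms at 512 Hz (410 samples); windows are sample-closed
(inclusive at grid-aligned endpoints, 0 ms = onset). Baseline correction
subtracts the −100…0 ms mean per epoch and channel and is idempotent.
Rejection removes an epoch when its range exceeds 100 µV on any channel.
Averaging produces the seven conditions; Position-1 deviants pool over the
following stimulus, and the global standard excludes block lead-ins and
standards after a Position-2 stimulus. The EFA matrix uses the −100…400 ms
crop (257 samples), realising the 500-ms analysis epoch.

## Temporal EFA

Rows of the data matrix are participant × channel × condition averages,
columns are time samples; all channels and all seven conditions enter by
default (both are configurable — the source is silent on the exact sets).

* **Factor count.** The Empirical Kaiser Criterion on the correlation
  matrix: reference `max(((p − Σ l_i)/(p − j + 1)) (1 + √(p/n))², 1)`,
  retained while the sample eigenvalue exceeds it.
* **Extraction.** Principal-component extraction from the covariance
  matrix (eigenvectors × √eigenvalue). The source only states "based on
  the covariance matrix"; PCA extraction is deterministic and requires no
  communality iteration.
* **Rotation.** Loadings are standardised by the column SDs *during
  rotation only*: Kaiser-normalised varimax (tolerance 1e−10), target
  `sign(B)|B|^κ` with κ = 3, oblique least-squares target rotation with the
  usual column normalisation, factor correlations Φ, then rescaling by the
  SDs to µV ("unstandardised loadings"). The reproduced covariance
  `Λ Φ Λᵀ` is invariant under the rotation to numerical precision.
* **Scores.** Thurstone regression scores in oblique form,
  `scores = centred data × Σ⁻¹ Λ Φ`, with a ridge fallback
  (ε = 1e−8 · trace(Σ)/p) for near-singular covariance (noiseless or
  rank-deficient fixtures).
* **Sign and peaks.** Each factor's sign is fixed so its peak loading is
  positive; the factor's peak latency is the argmax of the absolute
  unstandardised loading, fixed across conditions. The estimated peak
  amplitude is (ROI-mean score) × (loading at the peak); reading the
  extremum of the reconstructed waveform instead is available behind
  `at_extremum = TRUE`.
* **Contrasts.** Rule violation minus confirmation: Position-2 deviants low
  minus high repetition probability, Position-2 standards high minus low;
  plus Position-1 deviant minus global standard per rule, and the 2 × 2
  cell means (global × conditional rule) feeding the inclusion Bayes
  factor.

**A caveat on the EKC found while building the recovery suite.** With the
canonical narrow bumps, many time samples (baseline, late window) carry
essentially no signal. Columns of (near-)pure noise keep correlation-matrix
eigenvalues above 1 — the EKC's floor — so the criterion retains many
noise dimensions no matter how small the noise amplitude is (correlations
are scale-free). This mirrors the 23-factor solutions typical of real ERP
data. Exact k = 5 recovery is therefore demonstrated on a *coverage*
fixture whose five bumps (SD 45 ms, latencies −55…365 ms) span the whole
window; the narrow-bump truth is used for loading-congruence and
peak-amplitude recovery with k supplied. For the same reason the "k
non-increasing in noise" property holds only as a low/high-noise contrast:
at intermediate noise the EKC can transiently over-extract because the
weakened signal eigenvalues no longer consume enough variance to keep the
reference above the noise bulk.

## Behavioural generator and SDT analysis

Decisions follow an equal-variance SDT rule with a per-rule decision
threshold λ (`criterion`): on deviants, press iff `Normal(d′, 1) > λ` (and
no lapse, rate 0.01); on Position-2 standards, press iff `Normal(0, 1) > λ`.
The thresholds (1.462 / 2.085) and Position-2 sensitivities (3.522 / 3.904)
are chosen so the implied false-alarm rates (≈ 7%/2%) and biases
(c = λ − d′/2 ≈ −0.30 / +0.13) match the published behavioural summaries;
Position-1 sensitivities put raw detection at ≈ 0.995 so hit rates land
near 0.985 after lapses. Note the estimator recovers the *bias* c, not λ —
the recovery tests compare against λ − d′/2.

RTs for presses are lognormal with location `a · trial^b` (trial = 1-based
index of the deviant trial within the whole behavioural part) using
published posterior means as defaults, and log-scale SD
`exp(−1.75 + 0.30·pos2 + 0.15·pos2·high)` (≈ 0.17–0.28; the source does
not print its dispersion coefficients, these values give realistic RT
spread and the Position-2 widening seen in the data). Sampled RTs beyond
the 800-ms attribution window are recorded as misses and the truncation
rate is reported (< 0.1% at the defaults). Between-participant SDs
(a: 0.15 log-units, b: 0.002) are stated, not fitted — single-trial
variance components are not published.

Analysis side: presses are attributed to the most recent onset within
0–800 ms (windows are half-open since the SOA equals the window length;
first press wins, extra presses are logged), Position-2 rows after a missed
first deviant are excluded, rates use simple counts, the log-linear rule
`(k + 0.5)/(n + 1)` precedes the inverse-normal transform,
`d′ = z(hit) − z(fa)`, `c = −(z(hit) + z(fa))/2`, medians use the mean of
the central order statistics for even counts.

## JZS Bayes factors and design analysis

The Cauchy(0, r = √2/2) prior on the standardised effect is represented as
a normal scale mixture with inverse-gamma(1/2, 1/2) mixing; the Bayes
factor is an adaptive quadrature over the log-transformed mixing variable
(relative tolerance 1e−8, stabilised by the integrand's maximum). The test
suite checks it against a brute-force fixed-grid trapezoid oracle (10⁶
nodes) to 1e−6 relative error and against the shape constraints
(BF10(0) < 1, strict monotonicity in |t|, BF10 × BF01 = 1). Evidence
labels: > 3 moderate, > 10 strong, > 42 very strong (reciprocals for the
null); bounds exclusive.

The fixed-n design analysis simulates unit-variance normal paired
differences. With δ = 0.5, n = 60 and threshold 6 the hit probability is
0.832 (exactly: `P(|t_59(ncp 0.5√60)| ≥ t*)` with `BF10(t*) = 6` at
t* = 2.8895), above the planned 80%. The companion claim — a false-evidence
rate below 0.5% under δ = 0 — is *not attainable* for this two-sided Bayes
factor: exactly `2 pt(−t*, 59) = 0.539%`. The corresponding acceptance
expectation is deliberately left failing rather than loosened; a
directional Bayes factor would meet it, but one-sided tests are out of
scope here.

## The lognormal power-law RT models

Three nested models share a position × repetition-probability linear
predictor for log σ and differ in the location μ (log scale):

| model | μ |
|---|---|
| m0 | `1 + position * rep_prob + (1 | participant)` |
| m1 | `a · trial^b`, `a = 1 + position + (1|participant)`, `b = 1 + position * rep_prob + (1|participant)` |
| m2 | as m1 with `a = 1 + position * rep_prob + (1|participant)` |

Priors are weakly informative — `a` intercept Normal(log 300, 1), other
fixed effects Normal(0, 1), half-normal(0, 1) on the random-intercept SDs —
since the original informed priors live in an external analysis document.
Warm-up is half of the 6000 iterations (the split is unspecified at the
source). Random intercepts enter `a` and `b` only; σ has none.

**Sampler.** Posterior sampling is Hamiltonian Monte Carlo with analytic
gradients over all parameters jointly, a diagonal mass matrix estimated in
a warm-up window, dual-averaging step size (target acceptance 0.8) and a
jittered leapfrog length (31–60 steps). The joint update matters: μ =
a·t^b makes `a` and `b` strongly correlated a posteriori, and blockwise
random-walk Metropolis failed the convergence contract (Rhat < 1.01, ESS >
1000 on all monitored parameters) that `rt_fit()` enforces before
downstream summaries accept a fit without `force = TRUE`.

**Comparison.** PSIS-LOO (importance weights smoothed by a generalised
Pareto fit to the upper 20% tail, Pareto k reported, plain truncation when
k ≥ 0.7) with WAIC as cross-check, both from pointwise log-likelihoods on a
thinned draw set; lower LOOIC preferred. Bridge-sampling Bayes factors
between models are intentionally absent.

**Posterior predictive.** Group-level median-RT trajectories `exp(a·t^b)`
per cell over the trial grid, with 50/80/95/99% bands across draws. At the
published posterior means the Position 2 − Position 1 gap at trial 1 is
76.9 ms and the initial Position-1 median is exp(5.66933) = 289.9 ms.

## Numerical choices and degenerate inputs

* Windows are sample-closed; time 0 is stimulus onset.
* Configuration errors (infeasible packing, odd block counts under
  counterbalancing, non-integer repetition counts) raise structured errors.
* Zero-variance inputs error early (`bf_from_data`, `cohen_dz`,
  `dprime_c` on boundary rates); degenerate (constant-RT) model fits are
  flagged as non-converged rather than silently summarised.
* All randomness is seed-controlled; child seeds are derived arithmetically
  and stay below 2³¹.

## Known limitations

* The ERP generator's factor scores are participant-level constants; no
  trial-level amplitude variability or latency jitter.
* The EKC over-extracts on data with signal-free columns (see above) —
  consistent with its behaviour on real ERPs, but it means automatic
  factor-count selection cannot be validated against the narrow-bump truth.
* The RT likelihood ignores the (sub-0.1%) attribution-window truncation.
* Marginal evidences for Bayesian repeated-measures ANOVA are not computed;
  `inclusion_bf()` combines user-supplied evidences only.
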