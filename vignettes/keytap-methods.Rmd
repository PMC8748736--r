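---
title: "Methods: scoring and evaluating keyboard tapping tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and evaluating keyboard tapping tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keytap)
```

## The measurement problem

Bradykinesia — slowness of movement — is a cardinal motor sign of
Parkinson's disease (PD), conventionally rated by a clinician on the
0–4 integer finger-tapping item of the MDS-UPDRS part III. Integer
scales miss subtle change and inter-rater agreement is moderate, which
motivates objective keyboard tests that need no equipment beyond a
laptop:

* **DFT** (Distal Finger Tapping): tap the down-arrow key with the index
  finger as fast as possible for 20 s while the middle finger holds the
  left-arrow key depressed. The hold isolates movement to the index
  metacarpophalangeal joint, so the test measures *distal* movement.
* **BRAIN**: alternately tap `s` and `;` with one index finger for 30 s;
  movement arises at the elbow and shoulder, so this is a *proximal*
  measure.

From the raw press/release stream of one session `keytap` computes three
kinetic parameters:

| Parameter | Definition | Units | Abnormal direction |
|---|---|---|---|
| KS (kinesia score) | target-key presses inside the task window | taps | low |
| AT (akinesia time) | mean dwell time (press→release) over complete taps | ms | high |
| IS (incoordination score) | sample variance of travelling (flight) times | ms² | high |

Suffixes give the window (KS20 = DFT, KS30 = BRAIN).

## Scoring conventions

Several small conventions matter and are fixed here:

* **Window.** Half-open, `[0, 1000·window_s)` ms, anchored at the
  recorded test start (web tests begin with a countdown, not with the
  first press). A press at exactly the window end does not count.
* **Unreleased presses** (capture ended mid-dwell) count for KS — a
  keystroke happened — but are excluded from AT, and both adjacent
  travelling intervals are excluded from IS.
* **Travelling time is flight time**, release of tap *i* to press of tap
  *i+1*. Dwell and travelling phases are disjoint; a press-to-press
  definition would double-count dwell. Negative flight times (the next
  key registering before the previous release, a capture artifact on
  some keyboards) are excluded from IS while the taps still count for
  KS and AT.
* **IS uses the n−1 sample variance.** Counts per session are small
  (tens of intervals), so the unbiased estimator is preferred; the
  population-variance alternative differs by a factor (n−1)/n and is
  easy to derive from the reported counts if needed.
* **BRAIN alternation errors** (consecutive presses of the same key) are
  counted and reported but never subtracted from KS30; either convention
  can be reconstructed downstream.
* **Validity.** A DFT session is valid when the hold key covers at least
  90% of the window (`hold_threshold`, tunable); degenerate sessions are
  flagged with reason codes, never dropped silently.

## From sessions to the analysis table

Hand performance differs even in healthy controls, so a control's
analysis value is the mean of the left- and right-hand values. PD is
asymmetric, so a patient contributes the most affected side (recorded in
metadata; sides coded "equal" are averaged). Within a hand the first
valid trial is used — deployed tests record only the first successful
administration — and later trials feed the reliability analyses only.
Participants lacking a valid value keep their row with an absent entry
and the table records the per-column missing counts.

## The evaluation battery

* **Normality gate.** D'Agostino–Pearson omnibus K² for n ≥ 8 (the
  skewness normalisation needs 8 points), Shapiro–Wilk below; a sample
  is "normal" iff p ≥ 0.05. The gate selects unpaired t (equal
  variances) versus Mann–Whitney U for group comparisons, and paired t
  versus Wilcoxon signed-rank (gate applied to the paired differences)
  for On/Off contrasts. Summaries follow the chosen arm: mean (95% CI)
  or median (IQR). All significance is judged at the
  Bonferroni-adjusted α = 0.0025.
* **ROC analysis.** Empirical AUC with ties counted ½ (equivalently the
  Mann–Whitney U statistic divided by n₁·n₂), oriented so AUC is the
  probability that a random control scores more normally than a random
  patient. The 95% CI is DeLong's; sensitivity/specificity proportions
  get Wilson score intervals. Sensitivity at a fixed specificity uses
  the *most permissive* threshold achieving specificity ≥ target on the
  controls, with candidate cutoffs at midpoints between observed values.
* **Combination.** Logistic regression on z-standardised features
  (complete cases, dropped rows counted), scored by the *apparent*
  (in-sample) AUC of the fitted probabilities, with classification
  reported at 0.5 and 0.6 probability cutoffs. Perfect separation is
  flagged; coefficients are then reported as non-convergent but the AUC
  of the separating score remains valid. No cross-validation is done —
  the quantity mirrored is apparent discrimination.
* **Reliability.** ICC(3,1): two-way mixed-effects, consistency, single
  measure, computed from the ANOVA mean squares
  `(MS_S − MS_E) / (MS_S + (k−1)·MS_E)` on a complete subjects × sessions
  grid, banded per Koo & Li (<0.5 poor, 0.5–0.75 moderate, 0.75–0.9
  good, >0.9 excellent). Learning effects use the one-way
  repeated-measures ANOVA F = MS_sessions/MS_error without sphericity
  correction by default (Greenhouse–Geisser is available as an option).
* **Fluctuations.** Paired tests use each participant's *best* recorded
  value per state — the extreme in the clinically better direction
  (highest KS, lowest AT/IS) — a configurable reading of "best recorded
  state". The mixed model is
  `outcome ~ state + (1|subject) + (1|trial)`, REML, with crossed (not
  nested) random intercepts, Wald 95% CIs and Wald z p-values on the
  state coefficient. Wald intervals slightly undercover with 9 subjects
  relative to profile-likelihood intervals; this is a documented
  limitation, chosen to match common software defaults for this
  analysis. Singular fits (a variance component pinned at 0) are
  flagged, not errors.

## The synthetic cohort generator

No patient-level data are distributed with tapping-test publications, so
every analysis stage is exercised on simulated cohorts built from
printed group summaries.

**Subject layer.** Each subject draws a target triple
(ks_t, at_t, is_t). KS and AT targets are normal — both were analysed
parametrically in validation work — with SDs recovered from printed 95%
CIs via `sd = (half-width/1.96)·√n`; IS targets are lognormal matched to
the printed median and IQR (IS was analysed non-parametrically). The
default profiles encode the reference validation cohort: PD (n = 55)
KS20 55.0 (CI 48.9–61.1), AT20 195.6 ms (168.7–222.5), IS20 median
4589 ms² (IQR 1137–13464); controls (n = 65) KS20 89.3 (85.6–93.0),
AT20 105.5 ms (97.5–113.4), IS20 median 779.5 ms². A single standard
normal latent severity factor with loadings (−0.6 on KS, +0.6 on AT,
+0.6 on log IS) correlates the three parameters within subject; the true
correlation matrix is not published, so combined-AUC values from
generated cohorts are *not* calibrated to the published combination
results — only behavioural properties (combination never loses more than
0.02 AUC against the best single feature) are asserted.

**Feasibility.** Physically, the mean dwell plus the travelling-time
spread must fit the mean tap cycle `1000·window_s / round(ks)`: the
generator requires `10 ms ≤ at ≤ 0.9·cycle` and `√is ≤ 3·(cycle − at)`.
The printed PD marginals are not jointly realizable at full fidelity
(AT 195.6 ms with high-IS draws collides with a 364 ms cycle at 55
taps), so AT and IS are truncated to feasibility *conditionally on the
KS draw* — each parameter's idiosyncratic residual is redrawn given the
parameters already fixed. This keeps the KS marginal unbiased (the
headline discrimination figures rest on KS); generated PD AT means sit
roughly 5–7% below the printed marginal as the price of physical
consistency.

**Session layer.** A session for target (ks, at, is) emits exactly
`round(ks)` complete taps: dwells are drawn lognormal (CV 0.15) and
rescaled to sample mean exactly `at`; travelling times are drawn
lognormal and rescaled to sample variance exactly `is`, with the mean
travelling time set so the taps span 98% of the window. The lognormal
shape keeps flight times strictly positive even for large IS — a normal
shape would demand negative flight times once √is exceeds a third of the
mean gap. DFT sessions carry a hold-key event spanning the window, so
they validate at coverage 1.0. Scoring a synthesized session therefore
returns KS exactly and AT/IS exactly up to floating point — the
round-trip is the package's strongest self-check.

**Within-subject noise.** Session-to-session noise (defaults: KS ±5
taps, AT ±11 ms, IS ×e^N(0,0.19)) is a free parameter — only ICC bands,
not variances, are published — chosen to give test-retest ICC ≈ 0.9 for
KS, matching the reported "excellent" band. Clinical scores are
generated with signal: the finger-tapping subscore is a
monotone-decreasing noisy map of the subject's KS target (population
correlation ≈ −0.4 before integer rounding), and the part-III total
loads on the latent severity.

**Fluctuation layer.** Nine subjects by default complete eight tests at
90-minute intervals, states alternating Off/On with levodopa doses 30
minutes before each On trial. Each outcome is
`Off level + subject intercept + trial intercept + effect·[On] + residual`,
with Off levels and On effects taken from the published fluctuation
sub-study (KS20 62.78 → 71.78, i.e. +9.0 taps; AT20 −1.9 ms; IS20
on the log scale from medians 3452 → 1232; finger-tapping subscore
2.0 → 1.5, discretised to 0–8) and subject SDs recovered from the
printed CIs. Residual and trial SDs are free simulator parameters.

## What the simulations do and do not show

Passing tests demonstrate internal consistency: the scorer matches an
independent brute-force oracle; the generator's sessions score back to
their targets; AUC matches exhaustive pairwise concordance; ICC matches
the hand-computed ANOVA decomposition; the mixed model recovers planted
effects with near-nominal CI coverage; and a KS20 simulation
parameterised only by the printed means and CI-derived SDs reproduces
the headline discrimination (AUC ≈ 0.90, sensitivity ≈ 79% at 85%
specificity). They do not show that real keystroke data look like the
generator's output: real sessions carry fatigue and decrement within the
window, hardware-dependent latency and key-repeat artifacts, non-normal
hand asymmetries, and missingness patterns none of which are modelled.
Published values that depend on unavailable patient-level joint
distributions — the combined AUCs (0.95/0.92), the AT20/IS20 single-
parameter AUCs, the exact correlation r = −0.40, ICC point values
0.91–0.93 and the fluctuation p-values — are deliberately not asserted
as numbers; the corresponding machinery is covered by property checks
instead.

## Problem sizes and numerical choices

Monte-Carlo checks in the test suite use sizes chosen to keep each
statistical property sharp at desk scale: 1000 random sessions for
oracle equivalence, 500 synthesized sessions for round-trip fidelity,
10,000 draws per group for the headline ROC figures, 500 replicates for
mixed-model recovery and type-I calibration, and 1000 grids for the
RM-ANOVA null rate. Ties in AUC and rank tests are handled analytically
(½-counting, average ranks with normal approximation). Degenerate inputs
error early with named messages: zero-variance groups on the t-test
path, empty groups in ROC analysis, constant therapy state in the mixed
model, incomplete reliability grids. All simulator randomness flows
through R's global RNG, so a single `set.seed()` (or the CLI `--seed`
flag) makes every artifact byte-reproducible.

## Known limitations

* Amplitude and its decrement are unmeasurable from a keyboard; IS
  cannot be normalised to a coefficient of variation of travelling time.
* The generator matches printed *marginal* summaries; joint behaviour
  (parameter correlations, hand asymmetry magnitude, within-subject
  variance) is plausible but uncalibrated.
* Apparent (in-sample) AUC is reported for combinations, as in the
  mirrored analyses; expect optimism relative to out-of-sample
  discrimination.
* Wald inference for the mixed model is anticonservative at very small
  subject counts.
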