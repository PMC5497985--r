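---
title: "teplab: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{teplab: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what `teplab` computes and why the defaults are what
they are: the synthetic signal model, the electrophysiological estimators,
the behavioral scoring rules, the statistics layer, and the numerical
decisions that were genuinely open. Nothing here reports an empirical result
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The TMS-EEG signal model

### Protocol defaults

`protocol_config()` encodes a standard prefrontal LICI session: 2048 Hz
sampling, 50 single-pulse and 50 paired-pulse trials, a 100 ms
conditioning-to-test (CS–TS) interval, and FC4, FC6, F4, F6 — the
electrodes under the coil centre — as the analysis set. Epochs run from
−400 to +350 ms around the test pulse: the window must reach back past the
CS (−100 ms) to hold a pre-CS baseline, and forward far enough that the
shift-subtract correction (which reads the single-pulse response up to
`window end + 100 ms`) leaves the whole 50–150 ms analysis window defined.

All times are milliseconds relative to the test-pulse onset at *t* = 0. The
grid is built so that *t* = 0 is exactly on a sample. One consequence the
implementation has to face: 100 ms is **not** an integer number of samples
at 2048 Hz (204.8). The simulator therefore places the CS at the nearest
integer sample offset (205 samples = 100.098 ms) and `shift_subtract()`
snaps its shift the same way, so the correction cancels the CS response
exactly in noise-free data. Grids where the nominal interval is exact
(e.g. 256 or 512 Hz) are unaffected.

### The canonical evoked response

The ground-truth waveform (`tep_template()`) is a sum of Gaussian-windowed
cosines at the stereotyped TEP latencies — 20, 30, 45, 60, 100, 180 ms —
with amplitudes (+6, −4, +4, −3, −6, +3 µV) chosen so that

* a dominant deflection lies inside the 15–40 ms early-TEP window (so the
  early-TEP statistic has real signal to measure), and
* the N100 is the largest late component, as in published TEP waveforms.
  This matters quantitatively: LICI is quantified on the 50–150 ms window,
  and a realistic signal level there controls the rectification bias
  discussed in §2.

The response is causal (zero before the pulse). Channels scale by a crude
spatial falloff (`channel_gains()`): gain 1 under the coil, decaying with
distance, 0.2 for unknown sites. Paired-pulse epochs superpose the CS
response at −100 ms and a TS response multiplied by `1 − lici_true/100`;
`lici_true = 100` suppresses the test response entirely, negative values
produce facilitation.

### Noise

White Gaussian noise, independent per sample/channel/trial, with standard
deviation `noise_sd` (default 5 µV) — a plausible residual level for
cleaned, epoched EEG, and the simplest model that exercises the estimators.
After averaging 50 trials the ERP-level noise is 5/√50 ≈ 0.7 µV against
single-digit-µV signals. An optional 1/f-shaped variant
(`noise_color = "pink"`) with the same marginal SD exists for robustness
experiments. The generator does **not** model real TMS artifacts (decay,
muscle, blink), drifts, or any head geometry; passing recovery tests shows
the estimators are correct under this model, not that preprocessing of real
recordings is solved.

## 2. TEP and LICI estimation

Pipeline per subject: trial-average each condition, subtract the per-channel
mean over the baseline window, compute the early-TEP statistic from the
single-pulse ERP, apply shift-subtract, and form the inhibition ratio.

* **Baseline** −400 to −110 ms, ending 10 ms before the CS. The window must
  precede every pulse; overlaps are rejected rather than clipped.
* **Pooling order**: average trials → rectify → window statistic per
  channel → unweighted mean over the four coil channels. The windowed mean
  and the trapezoid AUC over the same window are proportional (ratio =
  window span), so both are reported and either can be used as "early TEP".
* **Quadrature**: composite trapezoid on the uniform grid; order-preserving
  and exact for piecewise-linear signals. Window endpoints are inclusive.
* **Undefined samples**: shifting the single ERP leaves the last 205
  samples without a counterpart; those samples are carried through
  unmodified, flagged, and excluded from *both* AUCs of the ratio so the
  comparison stays like-for-like. With the default epoch window the
  50–150 ms analysis window is fully defined and this never triggers.
* **Pulse artifact**: the first ~14 ms after a pulse are not used by any
  default window (early TEP starts at 15 ms; the LICI window at 50 ms). No
  interpolation is applied to synthetic data.

### Rectification bias

`E|x + noise| ≥ |x|`, so rectified AUCs are inflated wherever the signal is
small relative to the post-averaging noise — and the corrected-paired ERP
(signal × (1 − LICI/100), noise × √2) is always hit harder than the
single-pulse ERP. The ratio estimator therefore *attenuates*: at the default
noise level and a true 30 % inhibition the recovered mean is a few points
low (the acceptance suite measures this), and subjects with very small
amplitude scales attenuate more, which pulls cohort-level mean LICI below
the truth-parameter mean. This is a property of rectified-AUC inhibition
measures generally, not of this implementation; noise-free inputs recover
the truth to discretization error, which the tests assert at ±0.5 %.

## 3. Behavioral tasks

### Stop-signal

The simulator is a race-model agent: go RTs are Normal(`go_rt_mean`,
`go_rt_sd`) truncated at 50 ms; on stop trials a response escapes iff the
sampled go RT beats `SSD + ssrt_true`. SSD follows the one-up/one-down
staircase (+step after a successful stop, −step after a failure, floor 0),
which converges to 50 % stop success. Stop trials are laid out one per
block of `1/stop_fraction` trials at a random within-block position, so the
nominal 25 % fraction is exact by construction — a testability choice.
Trial count (400), initial SSD (250 ms) and step (50 ms) are documented
stand-ins: such designs rarely publish them, and they are configurable.

`estimate_ssrt()` uses the mean method, `SSRT = mean correct-go RT − mean
SSD`, the standard estimator for staircase designs; the integration method
is available behind a flag. Go errors are wrong-cue or omitted responses.

### Delay discounting

Choices are generated and fitted under the Mazur hyperbola
`V = A/(1 + K·D)` with a logistic decision rule
`P(delayed) = logistic(β · (V_delayed − V_immediate))`. The default item set
is the standard 27-item Kirby-style grid (immediate 11–80, delayed 25–85,
delays 7–186 days). Fitting maximizes the Bernoulli likelihood over a
41-point log-spaced K grid on [1e−5, 1] (β profiled by 1-D optimization at
each point, bounds [1e−3, 100]) and polishes the best point with L-BFGS-B
in log space. One-sided response patterns leave the likelihood flat beyond
the extreme item's indifference point, so no unique maximizer exists there;
the fit returns a plateau point and an honest `converged = FALSE`.

### Arithmetic and memory

A trial is *timely* if responded to within the 2000 ms deadline. Accuracy
divides accurate-and-timely trials by **all** presented trials (late or
omitted responses are failures — the natural convention for a speeded
deadline design); the timely-only denominator is available by flag since
either reading is defensible. Subjects with fewer than 3 accurate-and-timely
trials are flagged `discarded`. Memory is four-alternative forced choice
scored as proportion correct, chance 0.25; the simulated agent retrieves
with probability `p_mem`, else guesses uniformly (expected accuracy
`p_mem + (1 − p_mem)/4`).

## 4. The cohort generator

`simulate_cohort()` draws per-subject truth parameters from per-group
normal distributions (lognormal for K via `log_k`; hard-bounded parameters
truncated), questionnaire scores from a multivariate normal whose
correlation matrix honours the configured targets (identity elsewhere;
non-PSD targets are rejected with the offending eigenvalue), and task logs
per subject. Default groups are heavy users (SU, n = 16) versus nonusers
(NU, n = 35); group means use published group summaries where they exist
(SSRT 239/241 ms, go RT 583/601 ms, inhibition 29/26 %) and otherwise
encode the reported effect directions at moderate effect sizes (lower TEP
amplitude scale 0.8 vs 1.0 with SD 0.3, higher log-K, lower arithmetic
accuracy, higher ADHD-scale scores). The default cross-measure correlation
target is usage-frequency × inattention = 0.5.

Epoch arrays are deliberately not materialised inside the cohort object
(100 epochs × 10 channels × 1538 samples per subject); each subject carries
an `eeg_seed`, and `subject_epochs()` regenerates its epoch sets
deterministically. Everything — truth draws, scores, logs, epochs — is a
pure function of the master seed, which is what makes the byte-identical
reproducibility contract of the CLI possible.

## 5. Statistics layer

* **Outlier exclusion**: single pass, per group, per measure, at 2 sample
  SDs from the group mean; with n < 3 nothing is excluded. Iterative
  re-exclusion is deliberately off: the rule as usually stated is one pass.
* **Two-group test**: pooled-variance Student's *t* (df = n₁ + n₂ − 2 — the
  convention implied by reporting df = 49 for 16 + 35 subjects), Cohen's
  *d* with the pooled n−1 SD.
* **Mixed 2×2 ANOVA**: classical split-plot decomposition via `stats::aov`
  with an `Error(subject/time)` stratum; the between effect is tested
  against subject-within-group error, the within and interaction effects
  against the time×subject error; partial eta squared uses each effect's
  own error term. The test suite checks every SS term against an
  independent cell-means decomposition and SS conservation at 1e−10.
* **Bonferroni**: `min(1, p·m)` with the family size `m` an explicit
  parameter — published analyses are often ambiguous about the family, so
  it must never be implicit.
* **Post-hoc tests** after a significant interaction are paired/unpaired
  *t*-tests; exact tests for contingency tables are out of scope for
  continuous outcomes.

### A calibration caveat worth knowing

On clean normal null data the 2-SD exclusion step trims both tails,
shrinks the variance estimate while leaving the mean unchanged, and thereby
inflates the two-group type-I error rate roughly twofold above the nominal
5 %. The acceptance suite demonstrates both facts: with exclusion disabled
the test layer is calibrated (rejection 0.05 ± 0.02 over 1000 null
cohorts), and with the 2-SD rule the rate exceeds it. Users applying the
exclusion rule to well-behaved data should be aware they are trading
robustness for anticonservatism.

## 6. Problem sizes

The recovery studies run at sizes chosen to keep the full suite fast while
leaving Monte-Carlo error well inside the asserted tolerances: 100 subjects
for LICI recovery (noise 5 µV, truth 30 %), 100 seeds × 400 trials for
SSRT, 100 seeds × 135 choices for K, 1000 replicate null cohorts for
type-I calibration, 500 replicates for power, and 100 random templates for
the shift-subtract exactness property. Unit tests use smaller grids
(128–512 Hz) where only algebra, not statistics, is being checked.

## 7. Known limitations

* The epoch container is plain text (JSON sidecar + one CSV per trial):
  transparent and diff-able, but not suited to very large recordings; no
  vendor EEG formats are read.
* The signal model is stationary and artifact-free; no claim is made about
  preprocessing robustness on real recordings.
* The ANOVA supports exactly the 2 (group) × 2 (time) complete-case design;
  no imputation, no general mixed models.
* Rectified-AUC inhibition estimates attenuate under noise (§2); comparing
  groups with very different SNR can confound amplitude with inhibition.
* The discounting fit assumes the hyperbolic form; it does not arbitrate
  between discounting models.
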