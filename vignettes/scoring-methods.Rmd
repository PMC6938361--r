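---
title: "Scoring long-delay eyeblink conditioning EMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring long-delay eyeblink conditioning EMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debcr)
```

This vignette documents the scoring model `debcr` implements, the synthetic
data it validates itself against, and the design decisions taken where the
procedure leaves genuine freedom. It is the package's reference for *why*
things are the way they are; the README shows *how* to use them.

## The paradigm

Long-delay eyeblink conditioning pairs a 3350-ms tone CS with a 50-ms
periorbital-shock US whose onset comes 3300 ms after CS onset, so the two
co-terminate. A daily session is 12 blocks of 10 trials — 9 CS–US paired and
1 CS-alone per block, the probe's position randomized within the block — at
inter-trial intervals drawn uniformly from 25–40 s, over 7 daily sessions.
All times in the package are milliseconds relative to CS onset, which is
also how the latency measures are defined.

The package does not model the two-day habituation period (no stimuli are
delivered, so there is nothing to score), and treats the treatment-group
labels (saline, PCP, PCP-eNpHR, PCP-EYFP) purely as simulation metadata:
pharmacology and optogenetics are outside its scope.

## Trial scoring

Each trial is scored independently, from its own baseline:

1. **Rectify** the raw 10-kHz EMG (`|x|`).
2. **Integrate** with a 1-ms time constant. "Time constant" is the
   vocabulary of leaky integration, so the default is a first-order
   exponential filter `y[i] = a·y[i−1] + (1−a)·x[i]`, `a = exp(−Δt/τ)`,
   normalized to unit DC gain; a 1-ms causal boxcar is offered as a config
   alternative (`method = "boxcar"`) since the phrase is also used loosely
   for moving averages. The filter initializes at the first input sample —
   initializing at zero would put an artificial rising ramp inside the
   baseline window and bias the baseline statistics.
3. **Standardize** against the trial baseline, the half-open window
   [−300, 0) ms: the CS-onset sample itself is excluded, since "before CS
   onset" does not include the onset. SD uses the n−1 denominator; because
   the threshold is defined on the *standardized* trace from the *same*
   window, the choice of denominator cancels and the identity below holds
   either way.
4. **Threshold**: mean + 4·SD of the standardized baseline. Standardizing
   and thresholding on the same window forces the threshold to exactly 4
   z-units (the package asserts the identity to 1e−9 relative tolerance).
   The multiplier is configurable (`threshold_k`).
5. **Hyperactivity**: any supra-threshold baseline run longer than 10 ms
   invalidates the trial. Invalid trials contribute to no downstream count
   or metric except the accounting columns.
6. **Epoch detection**: maximal runs with `z` strictly above threshold,
   strictly longer than 10 ms (at 10 kHz: at least 101 samples, i.e.
   10.1 ms — a run of exactly 10.0 ms is rejected), with onset in the valid
   CR period 121–3292 ms.
7. **Windows**: short 121–1180, middle 1181–2240, late 2241–3292 ms. The
   printed integer bounds leave the open intervals (1180, 1181) and
   (2240, 2241) unassigned on a 0.1-ms sample grid; membership is
   implemented as [121, 1181), [1181, 2241), [2241, 3292], which partitions
   the valid period exactly and agrees with the printed bounds at every
   integer millisecond. An epoch belongs to the window containing its
   *onset* — the latency measures are onset-referenced, and this keeps a
   boundary-straddling epoch from being counted twice. A trial can be a CR
   trial in several windows only via distinct epochs.
8. **Metrics** per flagged window: start latency = earliest epoch onset;
   peak amplitude = maximum `z` over the epochs starting in the window;
   peak latency = time of that maximum, ties broken by earliest time.

### Numerical and degenerate-input choices

- Supra-threshold comparison is strict (`z > θ`), symmetric with the strict
  duration rule; with continuous noise the distinction is measure-zero.
- A flat baseline (zero SD) cannot be standardized. `standardize()` signals
  a classed error; `score_trace()` converts it into an invalid trial with
  `reason = "degenerate"` so a pipeline run never crashes on one bad trial.
  Accounting always satisfies `total = valid + hyperactive + degenerate`.
- "Peak amplitude during the CR period" is ambiguous between *the detected
  epochs* and *the whole window span*. The default scopes the peak to the
  detected epochs — crediting sub-threshold noise between epochs seems
  clearly unintended — but `peak_scope = "window"` implements the other
  reading.
- Nothing after 3292 ms is ever analyzed on paired trials: the valid CR
  period ends 8 ms before US onset, so the unconditioned reflex needs no
  artifact blanking. The trace is still simulated to CS offset for
  completeness.

## Session measures and their denominators

`CR% = 100 · n_CR / n_valid` within scope. The default scope is
**paired trials only** (the 12 CS-alone probes per session are excluded from
numerator and denominator), matching how per-session CR% is conventionally
reported for this design; `scope = "all_trials"` is available. A session
with zero valid in-scope trials has *undefined* CR%, reported as missing and
dropped by the statistics layer — never coerced to 0, which would fabricate
a floor effect. Likewise the conditional metric means (peak amplitude, start
and peak latency) exist only over CR trials and are missing when a cell has
none; nothing is imputed.

## Group statistics

The statistics layer mirrors how such data are conventionally analyzed: a
two-way mixed repeated-measures ANOVA (between: group; within: session), a
separate one-way RM-ANOVA, and Fisher LSD post hoc contrasts at α = 0.05.

- Sums of squares use the weighted cell-means decomposition; with one
  between factor and complete within data this coincides with the Type III
  solution, which matters because the emulated design is unbalanced
  (13/10/12/16 subjects). The implementation is verified in the test suite
  against `stats::aov(value ~ group*session + Error(subject))` to 1e−8 on
  balanced and unbalanced seeded designs.
- Group effects are tested against subjects-within-groups; session and
  interaction against the session × subjects-within-groups residual.
- No sphericity correction is applied by default (none is conventionally
  reported for this analysis); `gg_correction = TRUE` applies the
  Greenhouse–Geisser epsilon to the within-factor p values.
- LSD contrasts use the between-subjects error (rescaled to the
  subject-mean scale) for group pairs and the within residual for session
  pairs — standard mixed-design practice; the choice is declared rather
  than inferred, since the convention is not universal. p values are
  two-sided and uncorrected, which is what "LSD" means.
- Subjects missing any session are dropped with a message listing their
  IDs (complete-case); zero-error designs are returned as flagged
  degenerate fits, not errors.

## The synthetic cohort generator

The generator's job is to produce data with the statistical structure the
scoring procedure assumes, with known ground truth — not to be a
biophysical EMG model.

- **Carrier**: Gaussian white noise band-passed to 100–1000 Hz
  (second-order Butterworth, forward–backward) and rectified. This emulates
  the acquisition band-pass as a property of the simulated hardware; the
  analysis never re-applies it.
- **Bursts** (CR, UR, spontaneous blinks) are added at the envelope level
  of the rectified carrier, as unimodal kernels with a fast half-cosine
  rise, slower half-cosine decay, cubed to give the sharp apex of a real
  blink burst. Envelope-level injection is deliberate: the analysis only
  sees envelope statistics, and additive injection keeps the mapping
  between injected amplitude and measured z-amplitude linear. All
  amplitudes are specified in baseline-envelope-SD units via a one-off
  calibration of the noise model (`calibrate_envelope()`), i.e. in the same
  units as the detection threshold.
- **Acquisition**: per group and window, CR probability follows
  `p(s) = p_max / (1 + exp(−k(s − s0)))`. A trial draws *at most one* CR
  burst (the per-window probabilities partition the unit interval), keeping
  ground truth unambiguous; spontaneous blinks are a separate Poisson
  process (default 0.01 s⁻¹). CR onsets are truncated-normal within the
  window (SD 150 ms), positioned so the nominal supra-threshold start stays
  inside the window.
- **Ground-truth start latency** is recorded as the time the injected burst
  *alone* first exceeds 4 calibration SDs — the generating value of the
  quantity the detector is defined to measure. Recording the kernel's
  support onset instead would build the rise-to-threshold delay (tens of
  ms at moderate amplitudes) into every comparison as a phantom bias.
- **Hyperactive trials** are injected with a short (14 ms) 40-SD flat-top
  baseline burst. The shape is deliberate: the threshold is z-scored
  against the same baseline that contains the burst, so a long or moderate
  burst inflates its own baseline SD and deflates itself below threshold.
  The short/tall trapezoid is the construction that keeps "hyperactive by
  construction" true.
- **Defaults are illustrative, not fitted.** The emulated study reports its
  group curves only graphically, so the default `learning_model()`
  parameters were chosen once to reproduce the *orderings* it describes —
  saline above PCP in every window, PCP-eNpHR above PCP-EYFP, earlier
  late-window peak latency under PCP — and are not calibrated to any
  numeric curve. Asymptotic CR% defaults (e.g. saline: 15/30/45% across
  windows; PCP: 5/10/12%) are in the range a moderately trained cohort on a
  hard, long-ISI task plausibly shows.
- **Heterogeneity lives in the right layer.** The trial-level generator
  draws CRs iid Bernoulli within a subject-session cell, so ground-truth CR
  fractions converge to `cr_probability()` at binomial rate — the property
  the recovery tests rely on. Between-subject variance, which ANOVA
  calibration and power need, is added in the summary-level generator
  (`simulate_summary_cohort()`, subject offset SD 0.03 on the probability
  scale), which skips trace synthesis and makes thousand-replicate studies
  cheap.

### What the generator does *not* emulate

Real EMG has multiplicative (variance-modulated) bursts, motor-unit
structure, movement artifacts, electrode drift, session-to-session
impedance changes, and learning dynamics richer than a logistic in session
index (within-session learning, extinction on probes). Passing the
package's recovery tests therefore shows the *scoring rules* are
implemented correctly and are well-conditioned at realistic SNR — it does
not certify performance on any particular real recording.

## Validation problem sizes

The test suite validates at sizes chosen to give tight Monte-Carlo bounds
while keeping a full run comfortable on a laptop: detection equals a
brute-force run-enumeration oracle on 1000 random traces; sensitivity and
false-flag rates use 500 simulated trials each (6-SD bursts at default
noise); CR% and latency recovery use a 2-group × 4-subject × 2-session
trial-level cohort (~860 paired trials per group-session cell pooled);
type-I error uses 1000 Gaussian-null replicates of the full 51-subject ×
7-session design; power uses 200 summary-level replicates at the default
effect sizes. The acceptance script (`scripts/acceptance.R`) re-derives the
design constants — 120 trials, 9 paired per block, 3300-ms US onset, the
4-SD threshold and the 121-ms CR bound — from fresh runs of the installed
package.

## Known limitations

- The exponential-vs-boxcar reading of "1-ms integration" changes epoch
  durations near the 10-ms gate by fractions of a millisecond; both forms
  are provided, and the strict gate is applied identically to either.
- LSD error-term choices for unbalanced mixed designs vary across software;
  ours are stated above and tested for internal consistency, not for
  agreement with any specific package's convention.
- The CR-window boundary convention (half-open at 1181/2241 ms) matters
  only for onsets falling in two 1-ms gaps; on real 10-kHz data roughly 1
  onset in 1600 lands there.
- `simulate_cohort(keep_traces = TRUE)` holds ~290 KB per trial in memory;
  full-size cohorts (51 × 7 × 120 trials) should be streamed through
  `run_pipeline()` instead.
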