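---
title: "Measuring VOR and OKR learning from raw eye-position traces"
author: "vorlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring VOR and OKR learning from raw eye-position traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vorlearn)
```

## The measurement problem

In head-restrained mice, the vestibulo-ocular reflex (VOR) and the
optokinetic reflex (OKR) are probed with sinusoidal stimuli — turntable
rotation in darkness for the VOR, rotation of a striped drum for the OKR —
typically at 0.5 or 1 Hz with a peak velocity of ±10°/s.  The quantity of
interest is the *gain*: the ratio of eye-velocity amplitude to stimulus
peak velocity.  Motor learning is expressed as the percent change of the
response amplitude relative to a pre-training baseline (ΔVOR, ΔOKR).

The raw signal is eye *position* sampled uniformly (1000 samples/s by
default in this package).  Getting from there to a gain requires three
things done carefully: differentiation without amplifying sensor noise,
removal of saccades and movement artifacts that would otherwise inflate
the fitted amplitude, and a principled rule for discarding tests too
corrupted to measure.

## The measurement model

`measure_test()` implements the full chain for one 45 s VOR test or 50 s
OKR block:

1. **Low-pass filtering.** Position is filtered with a fourth-order 15 Hz
   Butterworth filter.  The filter is applied forward and backward
   (zero-phase) by default: this squares the magnitude response — which is
   still >0.9999 at 1 Hz — and introduces no phase lag, so the simulator's
   phase bookkeeping stays interpretable.  Whether the historical analyses
   this mirrors ran causally or zero-phase is generally not documented;
   the choice is exposed (`zero_phase = FALSE` gives the causal single
   pass) and is irrelevant for amplitude-based metrics at 1 Hz.
2. **Savitzky–Golay differentiation.** Velocity is the first derivative of
   a local order-2 polynomial fit over a 30 ms sliding window.  At 1 kHz
   that window is 30 samples; it is rounded to the nearest odd count (31),
   rounding up at ties.  The polynomial order is not something one can
   recover from a window length alone; order 2 with derivative order 1 is
   the standard choice for smoothed differentiation and its frequency
   response at the stimulus frequencies is within 0.1% of an ideal
   differentiator (the conditioning tests pin this down against the
   closed-form responses).  Endpoint samples are filled from the
   derivative of the terminal window's polynomial fit, so no samples are
   trimmed; any residual edge artifact is handled by the desaccading
   stage.
3. **First sinusoid fit.** Eye velocity is fit by ordinary least squares
   on the basis {sin 2πft, cos 2πft, 1} with *f fixed* at the stimulus
   frequency.  The intercept absorbs slow drift; amplitude and phase come
   from the two linear coefficients.  The first pass uses all samples —
   the exclusion rule is defined relative to an initial fit, so no prior
   mask can exist.
4. **Desaccading.** Samples deviating from that fit by more than 31°/s
   (strictly — a residual of exactly 31°/s is a tie and is retained) are
   marked as saccades or movement artifacts, together with 50 ms on each
   side (clipped at the trace ends, no wraparound).  Surviving retained
   runs shorter than 10 ms are then also excluded: fragments that short
   cannot constrain the refit.  The deviation is the *absolute* residual;
   "deviating by more than" a velocity is unsigned.
5. **Test rejection.** If more than 45% of the test's samples are excluded
   — counting everything excluded for any reason, padding and short
   fragments included — the test is invalid and contributes no amplitude.
   The inequality is strict: a test at exactly 45% is kept.
6. **Second fit.** Otherwise the sinusoid is refit on the retained samples
   only.  The amplitude of this second fit is the response amplitude;
   gain is amplitude / stimulus peak velocity.  Exactly two passes are
   performed.  Iterating mask/refit a third time changes the amplitude by
   under 0.5% on standard synthetic traces (a property the test suite
   documents without enforcing further iterations).

Two readings of the 10 ms segment rule are possible: it can refer to
surviving *retained* fragments (too short to help the fit) or to
*exclusion* runs (crossings too brief to be saccades, to be restored).
The package implements both behind `segment_rule`; the default is
`"retained"`, which matches the stated purpose of the rule — everything
short is *excluded*, not restored.  Similarly, whether the 45% denominator
counts padded samples is not something the rule's wording settles; here
the denominator is all samples of the test, and since the cutoff is a
fraction the choice only matters jointly with the threshold, which is
exposed in the configuration.

## Learning metrics

Amplitudes of the three valid tests of a VOR testing block are averaged
(`summarize_block()`); a block keeps its mean as long as at least one test
survives, and an all-invalid block yields an *absent* learning point,
never an imputed one.  `vor_learning_curve()` computes
100·(A<sub>t</sub> − A<sub>0</sub>)/A<sub>0</sub> against the time-0
baseline (just before training).  In pre-training protocols the blocks at
negative times are referenced to the session's initial (−30 min) block
instead, so each phase is expressed relative to its own start.

For OKR sessions (`okr_learning()`), the baseline is the mean amplitude of
blocks 1–3 and the post-training value the mean of blocks 58–60, with
intermediate points reported at blocks 10–50; block *k* sits at minute
*k* (50 s of training plus 10 s of darkness).

## Group statistics

`rm_anova_tukey()` is a univariate two-factor repeated-measures ANOVA
(between factor group, within factor time, subject = animal) fit via
`aov()` with `Error(subject/time)` strata, followed by Tukey-adjusted
pairwise contrasts on all group × time cell means (the usual family
definition) via **emmeans**.  Sphericity is reported, not assumed: the
Greenhouse–Geisser ε and corrected within-effect p-values appear next to
the uncorrected ones, and the significance flag uses the uncorrected p by
default, matching the way such designs are conventionally reported.
`shapiro_wilk()` screens normality; a failure is logged, not acted upon —
the parametric tests are reported regardless, so the screen is
informational.  `t_test()` covers the two-sample (pooled-variance) and
paired cases, with the degenerate identical-pair case reported as p = 1.

The pipeline's default comparison (`run_stats()`) feeds the ANOVA the
percent-change values at the post-training times only.  The baseline time
is excluded deliberately: Δ at baseline is identically zero for every
animal, a zero-variance cell that violates sphericity by construction and
inflates the uncorrected interaction type-I rate.  With baseline excluded,
the within-animal correlation induced by the shared baseline divisor is
close to compound symmetry and the uncorrected test is calibrated (the
acceptance suite verifies a ~5% empirical type-I rate over 200 simulated
null cohorts).

## The synthetic-data generator

`synthesize_eye_trace()` is the inverse model of the measurement chain:
eye velocity is the compensatory response −gain·stimulus velocity shifted
by a phase, plus half-sine saccade velocity pulses, white sensor noise and
a linear drift; position is the cumulative integral plus independent
position noise.  The half-sine pulse is smooth, integrates to the
step-like position change a real saccade produces, and has no parameters
beyond amplitude and duration.  `simulate_cohort()` stacks this into whole
sessions following the standard designs: VOR testing blocks of three 45 s
tests at times 0/10/20/30 min around three 10 min training blocks
(pre-training variants add −30/−20/−10 min), and OKR sessions of sixty
50 s blocks.

Defaults a scientist would recognize for this preparation, none of which
are published constants for this rig and all of which are configurable:

* sampling rate 1000 samples/s (typical for magnetic-sensor oculography;
  every time-domain parameter is converted to samples at run time);
* velocity sensor noise sd 2 °/s; saccade rate 1/s with amplitudes
  100–300 °/s and durations 20–80 ms, Poisson onsets thinned to
  non-overlap;
* between-animal variability as multiplicative log-normal jitter on the
  true gain, sdlog 0.05 (~5%), drawn independently at each testing time
  point.

What the generator does *not* emulate: blinks and gaps, pupil-tracking
artifacts, sensor calibration drift within a session, non-stationary
saccade statistics, and any real oculomotor plant dynamics beyond the
fitted sinusoid.  Passing recovery tests therefore demonstrates that the
analysis recovers what this forward model produces — unbiased to ~0.3%
under realistic noise — not that real recordings are free of other
artifact classes.

Because the jitter is part of the generated ground truth, recovery is
assessed against the *realized* per-cohort truth (the simulator records
the true gain of every test), not against the nominal group trajectory:
with five animals per group the jitter alone moves a group-mean Δ by a few
percentage points, which is biology in the model, not measurement error.

## Numerical choices and degenerate inputs

* The zero-phase filter pass runs in compiled code with odd-reflection end
  padding (3/cutoff seconds, ~200 samples at defaults); it matches
  `signal::filtfilt()` to 10⁻¹⁰ away from the edges, which the test suite
  asserts.
* The sinusoid fit solves the 3×3 normal equations; the basis is
  orthogonal enough over ≥1 stimulus cycle that conditioning is never an
  issue, and a retained span shorter than one cycle raises a classed
  degenerate-fit condition rather than returning a number.
* Exclusion-mask boundaries: padding is index arithmetic (50 ms × rate
  samples, rounded), and a retained run "spans" its sample count divided
  by the rate, so exactly 10 ms survives.  Ties at the 31°/s threshold
  and at the 45% cutoff are retained/kept (strict inequalities).
* Monte-Carlo sizes in the test suite (100 clean tests, 200 realistic
  tests, 1000 mask-oracle traces, 100 power and 200 null cohort
  replicates) were chosen so each check has narrow enough sampling error
  to be meaningful while the whole suite stays comfortably fast on a
  single core.

## Known limitations

* Phase is measured but no phase-based learning metric is provided; the
  learning curves are amplitude-only, as is standard for this paradigm.
* The RM-ANOVA is the univariate split-plot form; a mixed-model route
  would handle unbalanced data more gracefully (here, animals missing a
  time point are dropped from that comparison, with a warning).
* The 45% rejection rule interacts with the padding width: at high
  saccade rates most excluded samples are padding, so the effective
  artifact budget is roughly a third of 45%.
* Trace files are plain text for portability; at 45 s × 1 kHz they are
  ~2 MB each, so very large cohorts are better simulated in memory
  (`simulate_cohort()` → `analyze_cohort()`) than round-tripped through
  `run_simulate()`.
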