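---
title: "Simulating and analysing pitch-altered feedback experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing pitch-altered feedback experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchadapt)
```

## The problem

When speakers hear their own voice with the pitch (F0) shifted in real time,
most gradually shift their produced F0 in the opposite direction — a
sensorimotor adaptation that compensates for the perceived error — while a
minority follow the shift. Quantifying this behaviour runs into two
methodological problems that this package addresses end to end on simulated
data:

1. **Drifting voices.** Produced F0 commonly trends upward or downward over
   an entire session. Expressed relative to a single baseline average, that
   drift masquerades as adaptation (or hides it). The package implements a
   per-trial reference instead: a cubic polynomial in trial index fitted to
   the trials recorded with intact feedback.
2. **Individual pitch sensitivity.** Whether adaptation magnitude relates to
   how well a speaker can *hear* errors in their own voice requires
   measuring an own-voice F0 just-noticeable difference (JND). The package
   implements the full psychophysical machinery: stimulus selection from
   sustained-vowel recordings, a multi-QUEST Bayesian staircase, and a
   post-hoc d′-based refit.

Because the underlying participant data are not publicly deposited, every
stage is exercised on synthetic data from first-class simulators —
parametric speakers for the vocal sessions and parametric observers for the
forced-choice task — whose ground truth makes recovery testable.

## The session model

A session has 270 trials in four phases: 80 baseline, 10 ramp (the shift
grows linearly to its full magnitude), 100 hold (constant shift), 80
washout (feedback intact again). Three vowels (/a/, /e/, /o/) are scheduled
randomly with at least 3 occurrences of each per block of 10 trials. Each
trial's F0 track on a 10-ms frame grid is

\[
F0_{t,f} = B(t)\cdot 2^{\big(v_{\mathrm{vowel}(t)} + a_t + r_t + w_{t,f}\big)/1200},
\]

where \(B(t)\) is the baseline plus a cubic drift in trial index (Hz),
\(v\) are per-vowel offsets (cents), \(a_t \sim N(0, \sigma_a^2)\) is the
across-trial deviate, \(w_{t,f}\) is smoothed Gaussian within-trial noise
(correlation length about 50 ms, SD \(\sigma_w\) in cents), and \(r_t\) is
the response to the shift. The response follows first-order dynamics in
trial index: it relaxes toward \(-g \cdot s_t\) (gain \(g\), applied shift
\(s_t\) in cents) with time constant `adaptation_tau` while the shift is on,
and decays toward zero with `aftereffect_tau` during washout. A positive
gain opposes the shift; a negative gain follows it.

Choices worth recording:

* **Exponential response dynamics.** The empirical literature shows fading
  adaptation during hold and a short-lived after-effect but prescribes no
  functional form; a first-order exponential is the simplest form exhibiting
  both, and its closed-form window means give the tests exact oracles.
* **Cubic drift.** The drift term is drawn from the same model class the
  normalization fits, so the well-specified regime is exactly recoverable;
  an optional sinusoidal term (`drift_sine`) creates controlled model
  mismatch for sensitivity analyses.
* **Response constant within a trial.** The generator models adaptation
  (trial-scale), not within-trial compensatory corrections; consequently
  early and middle segment metrics differ only by noise in synthetic data.
  Passing tests therefore say nothing about compensation dynamics in real
  recordings — that contrast only exists in real data.
* **Cohort defaults** (`sample_cohort()`): characteristic pitch log-normal
  around 170 Hz; within-trial SD 40 cents and across-trial SD 30 cents
  (typical of sustained-vowel baselines); adaptation gains
  \(N(0.18, 0.54)\), matching a mean opposing response of ~18 cents against
  a 100-cent shift with large inter-speaker spread (about 60% opposing);
  observer thresholds log-normal around 40 cents (realistic spread of
  own-voice JNDs, roughly 10–300 cents); slopes uniform on [2, 4]; lapse
  rates up to 3%; a ~1 dB threshold penalty for downward pitch differences.

## Per-trial metrics and inclusion

F0 tracks are summarized per trial by the mean over the **first 100 ms** of
voicing (a feedforward read-out: auditory feedback corrections need longer
than 100 ms to act) and the **middle 100 ms** (where corrections may mix
in). "Middle" is operationalized as the window centered on the midpoint of
the longest contiguous voiced stretch — the source description never defines
it precisely. Trials whose longest voiced stretch is shorter than 400 ms,
or with no production, are excluded; exclusion drops a trial from reference
fits and window means but it still receives a reference prediction.
Unvoiced frames are excluded from means rather than interpolated, keeping
metrics independent of any interpolation policy.

The speaker's characteristic pitch is estimated from all pooled F0 points
(first tracking pass limited to 75–600 Hz) by least-squares fitting a
Gaussian to the histogram on a log-frequency axis with 10-cent bins; the
±6-semitone window around the fitted mean restricts the second tracking
pass, which is what suppresses octave errors. Fitting on a log axis rather
than in Hz avoids skewing the mean for wide distributions; the histogram
axis and estimator were open choices, decided here once.

## The normalization

For each metric, an ordinary least-squares cubic in trial index is fitted
to the segment F0 of the included baseline trials (1–80) and the last 50
washout trials (221–270) — the trials recorded with intact feedback on both
sides of the manipulated block. The curve predicts, for all 270 trials,
what F0 would have been had feedback stayed intact; trial values are then
expressed in cents relative to their prediction, with the sign flipped for
the upward-shift group so opposing responses are positive in both groups.
Zero hold-phase means are labelled "opposing" by convention (a measure-zero
tie).

Numerical details: the trial index is centered at 135.5 before raising to
powers (conditioning only — predictions are identical to the uncentered
fit); the fit requires at least 20 usable anchor trials; degrees 0–3 and
shorter washout anchors are exposed (`degree`, `washout_anchor`) for the
sensitivity analyses that motivated the cubic/50-trial default, and
`single_value_reference()` provides the traditional single-value baseline
for comparison. Per-vowel hold means weight trials equally (trial-count
weighting), and the washout windows (first 30/8/5 trials) are literal trial
ranges regardless of vowel composition.

## The JND engine

Pitch differences are expressed on an "interval dB" scale,
\(x = 10\log_{10}(\Delta\,\text{semitones})\), mapping 1 cent to −20 dB and
100 semitones to +20 dB. The threshold grid spans that range at 0.01 dB
(4001 points) with a deliberately uninformed Gaussian prior (mean 10.8 dB =
one octave, SD 80 dB). Four QUEST posteriors run in parallel with Weibull
slopes β = 1–4, each using the Watson–Pelli form

\[
p(x) = \delta\gamma + (1-\delta)\Big(1 - (1-\gamma)e^{-10^{\beta (x - T + \epsilon)}}\Big),
\]

with γ = 0.5 (3I-2AFC chance), δ = 1% during the staircase, and ε solved in
closed form per β so that \(p(T) = 0.70707\) — the threshold parameter
always denotes the same percent-correct point. After each trial all four
posteriors are updated in log space; the best guess is the grid mode of the
posterior whose normalized peak is highest, and the next trial is placed at
the best guess plus a uniform ±5 dB rove (clipped to the grid), with the
sign of the pitch difference drawn equiprobably. Runs last 210 trials, and
a practice gate (20 trials at 4.8 semitones, pass above 80% correct)
precedes the test. Up and down trials update one shared posterior on the
magnitude; directions are separated only in the post-hoc refit.

The named Weibull parameterization is the one consequential place where the
procedure's description underdetermines the formula; it is isolated in
`weibull_p()` so alternates can be swapped. "Likelihood maxima" are
implemented as posterior maxima (the prior is so flat that the two are
near-identical, and the procedure is posterior-based by construction). The
placement rove is uniform, out-of-grid roves are clipped rather than
redrawn, and all grid ties break toward the smaller threshold (a
conservative JND) — each of these was unstated and fixed here once.

After the run, the history is refit separately for positive and negative
pitch differences over 25 parameter pairs: lapse rates 1–5% crossed with
five slopes at 0.2 steps centered on the staircase's final slope, reusing
the staircase prior (whether the original refit was prior-weighted is
unstated; with this prior the influence is negligible). The winning pair is
the one with the highest normalized posterior peak. Hit rates are read off
the positive fit, false-alarm rates as one minus the negative fit, both
clamped to [0.001, 0.999], and combined as
\(d'(x) = z(H(x)) - z(F(x))\). The JND is the smallest level with
\(d' \ge 0.77\), linearly interpolated and converted to cents; 0.77 is the
2AFC convention \(\sqrt{2}\,z(0.70707)\), which `dprime_criterion()`
verifies as a standalone computation. Curves that never reach the criterion
report an unmeasurable (beyond-grid) JND rather than a number. Per-vowel
JNDs rerun the whole refit on each vowel's trials; the observer model
exposes an optional per-vowel threshold bias so planted vowel effects are
testable, without asserting any mechanism for real listeners.

The simulated observer answers through the same Weibull family with its own
threshold, slope and lapse, a threshold offset for negative differences
(listeners are typically poorer with downward targets), and the optional
vowel bias. Using the calibrated form means `true_threshold` is exactly the
observer's 70.707% point, which makes recovery errors interpretable in dB.

## The stimulus builder

For completeness the acoustic path of the forced-choice task is
implemented: the Hilbert envelope of a recording (analytic-signal magnitude,
smoothed by a 10-ms moving average to remove pitch-period ripple, decimated
to 1-ms frames, in dB re peak), the voiced window cut 10 dB below the peak,
a random search for a 300-ms segment whose envelope-level SD is at most
3 dB (10 candidate onsets, then the recording is abandoned), 30-ms cosine
gating, F0 flattening by resynthesizing the segment's harmonic content at a
constant F0 under its own slow amplitude contour, a reference F0 roved
uniformly on 150–200 Hz, the target (reference × \(2^{\Delta/12}\)) in
interval 2 or 3 equiprobably, and independent ±3 dB level roves per
interval around a fixed digital calibration level (−26 dBFS RMS standing in
for 65 dB SPL, which is meaningless without hardware). The same segment
fills all three intervals of a trial, and the envelope frame rate is 1 ms —
both unstated in the source description and fixed here. For
simulated-observer experiments the acoustic path is bypassed entirely
(`build_triplet(audio = FALSE)` carries the roves and F0s symbolically);
the audio path exists for fixtures and demonstrations.

## Problem sizes and numerical choices

The test-suite simulations use: 50 observers for the full-chain JND
recovery check (median |error| and rank correlation), 200 seeds per planted
gain for the unbiasedness check, 50 seeds per sign for the
opposing/following label check — run at a 200-cent shift so that the planted
effect (60 cents) clears three standard deviations of the hold-mean
estimator (~14 cents under the default noise), the regime in which labels
are claimed to be reliable — and 20 independent cohorts of 59 for the null
JND–adaptation correlation. These sizes keep every check honest while the
whole suite runs in minutes on one core; the cohort size of 59 matches the
study design the pipeline emulates.

Other numerics: posterior bookkeeping is in log space with explicit
normalization on read-out; the likelihood grid scan exploits exact
saturation of the Weibull curve in double precision (far below the tested
level the curve equals its ceiling bit-for-bit, far above it equals γ), so
restricted evaluation windows change nothing but speed; the 25-pair refit
scan is compiled (Rcpp) because it sits inside cohort-level simulations;
probabilities are clamped to [1e−12, 1−1e−12] before logging in the generic
update (relevant only for zero-lapse configurations); and the Gaussian
histogram fit falls back from `nls` to moment estimates if the optimizer
fails, and short-circuits for point-mass histograms.

## Limitations

* The generator produces stationary, fully voiced vocalizations with
  Gaussian variability; creak, voice breaks, coughs and visible-screening
  exclusions are not modelled (the 400-ms rule is exercised by
  construction, not by realistic pathology).
* No real-time feedback loop, masking noise, or PSOLA pitch extraction: the
  autocorrelation tracker is plumbing for synthetic audio, not a
  replacement for production pitch tracking.
* Mixed repeated-measures ANOVAs (and sphericity corrections) are out of
  scope; summaries are exported in long format so any statistics
  environment can run them.
* Trial-to-trial autocorrelation of produced F0 beyond the drift term is
  not asserted; the within-trial correlation length is a parameter, not an
  empirical claim.
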