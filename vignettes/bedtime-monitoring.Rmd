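---
title: "Bedtime fall detection and prevention: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bedtime fall detection and prevention: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedwatch)
```

`bedwatch` models a two-sensor bedtime monitoring system: a waist-worn IMU
for falls and bed-exit movement, and three under-mattress pressure strips
for bed position. This vignette explains the detectors, the parameters that
matter, what the simulator does and does not emulate, and the design
choices made where the underlying firmware semantics were open.

## The fall state machine

The on-sensor detector is a three-phase state machine over the acceleration
signal vector magnitude $\mathrm{SVM} = \sqrt{a_x^2 + a_y^2 + a_z^2}$:

* **SAMPLING** — waiting. A sample with $\mathrm{SVM} > 2.5$ g (strictly)
  arms a capture and starts the log with that peak sample.
* **POST_PEAK** — capture. Samples are appended to the log until the first
  sample strictly later than *peak time + 1000 ms*.
* **POST_FALL** — quiescence check, 1500 ms. A new supra-threshold sample
  clears the log and restarts the capture from that sample — repeated peaks
  look like running, not a fall. An uneventful deadline emits a
  `FALL_EVENT` carrying the captured window.

All comparisons are strict (`>`), so a sample exactly at a threshold or a
deadline does not trigger; the boundary cases are pinned by unit tests. The
re-trigger transition resets the capture deadline from the new peak, so a
burst of activity keeps postponing the decision rather than reusing a stale
deadline. `fall_step()` is the reference single-sample transition;
`detect_falls()` replays it over a whole stream with an inlined loop, and
the test suite proves the two equal — and both equal an independent
whole-trace enumeration of threshold crossings and quiescence windows — on
a thousand random traces.

## The 13 features and the classifier

Each captured window is summarised into 13 features: SVM mean and variance;
y- and z-axis acceleration and angular-velocity means and standard
deviations; fall time; and one spectral coefficient per magnitude series.
The x axis is deliberately absent from the per-axis statistics: worn at the
waist with x vertical, that axis mostly carries gravity, while the y/z
statistics capture the orientation change that distinguishes a fall from an
upright jolt.

Three conventions were genuinely open and are fixed as follows:

* **Population statistics.** Windows are complete captured signals, not
  samples from a population, so variances and standard deviations divide by
  $N$. This also makes small hand-computed test cases exact.
* **Fall time** is the span from the first sample of the log (the
  triggering peak) to the last sample whose SVM still exceeds the trigger
  threshold, and 0 when only the peak exceeds it. It measures impact
  duration using only quantities the firmware logs.
* **Fourier coefficient** is the largest non-DC magnitude of the DFT of the
  mean-removed magnitude series, scaled by $2/N$ so that a sinusoid of
  amplitude $A$ (integer periods in the window) yields exactly $A$ — a
  single amplitude-interpretable scalar. A closed-form sinusoid test pins
  the normalization.

The classifier is a soft-margin support-vector machine (linear kernel by
default, radial available; cost 1). Features are z-scored with training-set
statistics; a zero-variance training feature maps to 0 instead of dividing
by zero. The fitted object stores the support vectors, dual coefficients
and intercept itself and predicts from them, so a model saved to JSON (full
numeric precision) reloads bit-stably; a test cross-checks these
predictions against the fitting library's own `predict()` on both kernels.
Training is deterministic: the same dataset yields a byte-identical model
file.

## Bed position: rule cascade and debouncing

Each pressure sample `(left, middle, right)` passes through an ordered
if/else cascade — empty bed, lying middle, sitting left, lying left,
sitting right, lying right — with first-match semantics; anything that
matches no rule (including exact ties under the strict inequalities) is
`NOT_RECOGNIZED`. Two predicates are parameterised because raw counts are
hardware-dependent: *near zero* (default 5% of the 1023-count full scale)
and *a large difference* (default 40%). `diff` is the absolute difference
throughout. The left and right branches are mutually exclusive, so the
cascade is left/right symmetric; a property test over random samples checks
that swapping the channels mirrors the label.

Transitions between postures produce unreliable readings, so the raw label
stream is debounced: `NOT_RECOGNIZED` is dropped outright (no change of
position is considered), and a new label becomes the stable position only
after persisting strictly longer than 1 s, measured from the first sample
of its run. Debounced output therefore never contains `NOT_RECOGNIZED` and
never repeats a position.

## Movement detection and fusion

Standing shows `ax` above 0.9 g with `az` inside ±0.4 g; lying shows the
reverse (x near 0, z near 1 g). The posture test uses only these two
components — y would reveal the exit side, which is irrelevant for an
alarm. Because the test holds continuously while the wearer stands, raw
emission would fire every sample; `detect_motion()` therefore emits an
event whenever the test holds and no event fired within the last 2 s. This
rate-limited semantics is what the fusion stage consumes: one event per
episode of standing, re-emitted only if standing persists past the rearm
window.

The fusion monitor merges stable-presence and movement events by timestamp.
`NO_PRESENCE` alarms unconditionally (`BED_EXIT`); a sitting position with
movement within the preceding 2 s alarms as `EXIT_INTENT`; lying never
alarms. The 2 s recency window gives "sitting *and* movement" a
well-defined meaning, since the two streams share nothing but timestamps.
Each presence episode alarms at most once and re-arms when the position
changes — a caregiver needs one notification per incident.

## The simulator

No public dataset exists for this sensor pairing, so the package carries
seeded generators for every input the detectors consume. They emulate the
validation protocol: nine activities (four fall directions; hit, jump,
run-and-stop, sit, pull), bed exits from either side with the three-phase
lying–sitting–standing acceleration profile, in-bed rolling as the
negative control, and pressure sequences over the six positions.

The published material constrains thresholds, phases and qualitative
shapes, but no waveforms, so the signal shapes are package inventions kept
as simple as the constraints allow: half-sine impact transients, logistic
orientation cross-fades, Gaussian noise, linear pressure fades. Key
defaults and why:

* impact peaks ~N(3.2, 0.4) g truncated above 2.6 g (backward falls softer,
  ~N(2.8, 0.2) truncated above 2.55), so every fall clears the 2.5 g
  trigger by construction;
* post-impact quiescence 3000 ms ≥ the 2500 ms capture-plus-quiescence
  horizon, so every fall trace completes its check in-trace;
* running peaks every 1500 ms < 2500 ms, so running cancels pending
  captures until the final stop;
* sitting down shares its transient amplitude, semi-reclined end
  orientation and gyroscope signature with the backward fall — this is the
  documented hard case, and the held-out test asserts that backward falls
  are the most-confused fall class rather than pretending the two are
  separable;
* pressure levels per position (e.g. lying middle `(300, 700, 250)`,
  sitting left `(900, 300, 0)`, mirrored on the right) satisfy their target
  rule with margins of at least five noise standard deviations
  (noise sd 10 counts), so the six-position battery is recovered exactly at
  default noise; cross-fades last 400 ms, safely under the 1 s debounce;
* bed-exit IMU phases: lying 3 s, transition 1 s, sitting 2 s, transition
  1 s, walking 1.3 s — the posture test first holds mid-way through the
  sitting-standing transition, and the trace ends before the 2 s rearm
  window elapses, so one exit yields one movement event.

What the simulator does **not** emulate: real impact biomechanics,
sensor drift and saturation, the asymmetric strip sensitivities seen in
hardware, or genuinely adversarial ADLs. Passing tests on simulated data
therefore demonstrate the *logic* of the detectors — trigger semantics,
debounce behaviour, fusion ordering — not field performance; the published
human-subject rates enter the package only as fixture tables.

## Evaluation conventions

Accuracy is `(TP+TN)/total`; the published headline numbers (93.51 / 92.04
/ 95.45) are consistent only with this standard formula, which the package
uses throughout. Ill-defined metrics (zero denominators) raise errors
rather than returning 0, because silent zeros corrupt macro means. Report
output rounds half-up to 2 decimals; tests compare at 0.01 percentage
points, which also absorbs the one printed value that was truncated rather
than rounded (a sitting-side sensitivity of 6/11). The independent-stage
combination multiplies stage fractions at report precision, mirroring the
published arithmetic.

## Problem sizes

The test suite and acceptance script run at desk scale: 1000 random traces
for the oracle-equivalence property (~80–220 samples each at 50 Hz), 40
simulated bed exits and 40 rolling traces for the movement-detector rates,
8 repetitions per activity for classifier training and 5 for held-out
testing. These sizes keep the full suite under a minute while leaving each
property statistically meaningful at the logic level.

## Known limitations

* The pressure full scale and the near-zero / large-difference thresholds
  are configuration, not measured constants; real installations need
  calibration.
* The lying-left branch of the cascade, taken verbatim from the firmware
  logic, lacks a `middle > right` guard; the symmetry property still holds,
  and the case is flagged rather than silently corrected.
* The classifier is only as good as the simulated protocol; no claim is
  made about transfer to real falls.
* Timestamps are integer milliseconds; sub-millisecond jitter is out of
  scope, and streams from different sensors are assumed roughly
  synchronized (the fusion window tolerates ~2 s of skew).
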