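---
title: "T-wave time-warping markers for personalised blood-potassium monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{T-wave time-warping markers for personalised blood-potassium monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

End-stage renal disease patients on hemodialysis swing through large blood
potassium excursions between sessions: [K+] falls steeply while dialysate
clears it and creeps back up over the following one to two days. These
swings are arrhythmogenic and clinically silent. The earliest ECG
correlate of rising potassium is a narrowing and peaking of the T wave, so
a sufficiently sensitive, patient-specific measure of T-wave morphology
change can act as a noninvasive potassium sensor between blood draws.

`kwarp` implements such a sensing chain end to end:

1. zero-phase Butterworth preprocessing of a multi-lead Holter ECG;
2. a spatial lead transformation (periodic component analysis) that
   concentrates the beat-to-beat *periodic* T-wave content into one
   derived lead, piC1;
3. time-warping comparison of mean T waves in 2-minute windows against a
   reference window at dialysis end, yielding the markers dw (signed mean
   warping, ms) and dw,c (its heart-rate-corrected version);
4. per-patient, monotonicity-constrained polynomial models mapping the
   marker to the potassium variation relative to dialysis end,
   `delta K(h) = K(h) - K(h4)`, evaluated with all-samples and
   leave-one-out rules.

Because no public dataset pairs long Holter recordings with serial blood
potassium, the package ships a synthetic session generator with analytic
ground truth; every stage is validated against quantities the generator
knows exactly.

## The measurement model

### Windows and the mean warped T wave

T waves from piC1 are low-pass filtered at 20 Hz (6th-order, zero-phase)
and collected in 2-minute windows centred on the 5th and 35th minute of
each recorded hour. Within a window, waves are screened (duration more
than 25% away from the window median, or correlation below 0.95 with the
window average, flags a beat out; flagged beats are excluded, never
interpolated) and summarised by a mean warped T wave (MWTW): an iterative
warped average initialised from the wave of median duration, time-scaled
to the mean duration of the window, iterated until the template changes by
less than 1e-3 in relative sup norm (at most 10 rounds).

### The warping distance

Two waves are compared in the square-root-slope-function (SRSF)
representation. Both are mapped to normalised time [0, 1] and resampled on
a common grid (0.5 ms step on the reference support); the optimal monotone
warping minimising the SRSF misfit is found by dynamic programming over
piecewise-linear lattice paths with coprime slope steps up to 4, with the
diagonal preferred on cost ties so that identical waves map to the exact
identity. The warping is boundary-anchored: T onset maps to T onset and
T end to T end, so a pure duration change appears as a straight warping of
slope equal to the duration ratio.

The unsigned marker is the mean absolute deviation of the de-normalised
warping from the identity, in milliseconds; for a pure scaling by `s` this
is `|s - 1| * T_ref / 2` exactly, which the tests use as a closed form.
The signed marker dw attaches the direction of the deviation.

**Sign convention.** The package's default makes *narrowing positive*: a
test wave narrower than the dialysis-end reference (the hyperkalemic
direction) gives dw > 0. This is the convention under which the marker
increases with the potassium excess, matching the observed positive marker
values at dialysis onset and making the monotone-increasing sensing models
below directly applicable. The opposite convention is available via
`warp_pair(..., sign_convention = "widening")` and the pipeline
configuration.

### Heart-rate correction

T-wave duration also tracks the RR interval. The corrected marker removes
a Bazett-like component,

`dwc(t) = dw(t) - c_hat * (sqrt(RR(t)) - sqrt(RR_ref))`,

with `c_hat` fitted per patient by least squares on a late post-dialysis
stability segment (default: the trailing 4 h of the recording, where
potassium-driven marker dynamics are low, so residual marker movement is
attributed to heart rate). If the segment is unusable the correction
degrades gracefully to `c_hat = 0`. On heavily compressed synthetic
sessions (shortened for test budgets) the stability assumption does not
hold and the correction can overfit; the corrected marker is therefore
exercised mainly through construction-based unit tests where the RR-driven
component is known.

### The lead transformation

Periodic component analysis finds the spatial projection `w` minimising

`eps(w) = E || w'x(t') - w'x(t) ||^2 / E || w'x(t) ||^2`

where `t` runs over each beat's T-wave segment (mode piCT; the whole QRST
in mode piCB) and `t'` is the time-aligned sample one beat later; segments
are linearly resampled to a fixed length (400 samples for T waves, 600 for
QRST) so one-beat periodicity remains defined while RR drifts. Stationary
points solve the generalized eigenproblem `A w = lambda B w` (difference
covariance vs total covariance); components are ordered by ascending
eigenvalue, so piC1 is the most periodic derived lead, and each component
is sign-fixed so its median T-peak amplitude is positive, making the whole
pipeline deterministic. The transform is estimated once per recording from
all delineated beats. If the leads are exactly linearly dependent (the
total covariance is rank deficient), the problem is solved on the
non-degenerate subspace with a warning; a null covariance aborts.

### The sensing models

For each patient and marker `d`, intercept-free polynomials

- linear: `delta K = alpha * d`
- quadratic: `delta K = alpha * d + beta * d^2`
- cubic: `delta K = alpha * d + beta * d^2 + gamma * d^3`

are fitted by least squares with all coefficients constrained
non-negative (Lawson-Hanson non-negative least squares on the Vandermonde
design), which guarantees a monotone non-decreasing estimate for positive
markers — the physiologically admissible direction. There is no intercept
because both the marker and `delta K` vanish at the reference by
construction. Negative marker values, which occur as outliers, are kept in
the fit and not clamped.

Two estimation rules are computed: `a` (train on all six hours) and `o`
(leave-one-out: each non-reference hour is predicted from a model fitted
without it; the reference h4 stays in every training set because it
anchors the model, and it is excluded only from error evaluation, where
both the measurement and the estimate are identically zero). Evaluation
reports per-patient Spearman and Pearson correlations over the six hours
(the reference point included by default; configurable via
`include_reference_in_corr`) and the errors `e(h) = estimate - measured`
at the five non-reference hours, aggregated across patients as the median
of |e| with the 25th-to-75th-percentile range (linear interpolation) of
the signed errors, pooled and segregated at the first and last hours.

## The synthetic session generator

`generate_session()` emulates the study conditions: a 48 h, 1 kHz, 8-lead
(I, II, V1-V6) Holter session spanning a dialysis treatment, with six
blood-sample hours h0..h5 (dialysis onset, hourly during treatment,
dialysis end at minute 215 as reference, and just before the next
session). Its components:

- **Template beat.** Piecewise analytic: Gaussian P, Q, R, S deflections
  and a raised-cosine T lobe. An analytic template keeps every landmark in
  closed form. The stored ground-truth T fiducials are the *tangent-rule*
  landmarks of the lobe (the steepest-slope tangents cross the baseline at
  fractions 1/4 - 1/(2 pi) and 3/4 + 1/(2 pi) of the support): these are
  the landmarks an ideal tangent delineator recovers, they scale exactly
  with the lobe duration, and — unlike the support endpoints of a smooth
  lobe, where the slope vanishes — they are recoverable from sampled data.
- **Potassium trajectory.** Defaults to 5.6 mmol/L at onset falling to
  3.6 at dialysis end and recovering to 5.2 before the next session, the
  canonical interdialytic shape; knots are interpolated piecewise
  monotonically (Fritsch-Carlson within each monotone run).
- **Coupling.** T duration is scaled by `1 + width_gain * delta K(t)` with
  `width_gain = -0.05` per mmol/L by default (higher potassium, narrower
  T wave); amplitude analogously with `amp_gain = +0.05`. The literature
  describes this transfer only qualitatively, so the gains are free
  simulation parameters chosen to produce marker excursions of a few milliseconds
  over a typical 2 mmol/L excursion — not estimates of human physiology.
- **Rhythm and noise.** Mean RR drifts 850 to 950 ms across the session
  with 2% multiplicative beat-to-beat jitter; each lead receives the
  single cardiac source through a fixed mixing vector plus lead-specific
  baseline wander (100 uV at 0.3 Hz by default) and white noise
  (20 uV SD).

What the generator does *not* emulate: ectopy and rhythm disturbance,
multi-source spatial structure (one dominant source only), electrode
motion artefacts, T-wave alternans, and any direct RR-to-T-width coupling.
Tests passing on this generator therefore demonstrate the correctness of
the measurement chain under its stated model, not robustness to every
property of clinical recordings.

`simulate_marker_cohort()` complements the signal-level generator at the
cohort scale: patients are simulated directly at the marker level with
known non-negative polynomial coefficients linking `d` to `delta K`
(defaults: linear coefficient 0.08-0.16, quadratic 0.004-0.012, i.e. a
mildly nonlinear truth), a canonical marker trajectory (12, 4, 2.5, 1.5,
0, 10 ms at h0..h5 — mid-dialysis values clustered low, the
dialysis-onset and next-session values isolated at the top of the range,
matching the uneven marker distributions observed in practice) scaled
per patient by a uniform factor 0.6-1.4, and Gaussian potassium
measurement noise of 0.2 mmol/L SD. The h5 marker additionally receives a
patient-specific multiplicative shortfall (uniform on 0.75-1 by default):
ambulatory recordings typically end hours before the next-session blood
draw while potassium is still rising, so the marker available for h5
underestimates the one matching its potassium value. This
desynchronization is what makes h5 — together with the extrapolated h0 —
the hour with the widest leave-one-out error spread. This is what the
model-level validation (coefficient recovery, all-samples vs
leave-one-out patterns) runs on.

## Numerical choices

- **Filters.** Butterworth designs are realised as cascaded second-order
  sections from the analog prototype via the bilinear transform; at a
  0.5 Hz cutoff and 1 kHz sampling, the expanded transfer-function
  polynomial is numerically unusable in double precision while the biquad
  cascade matches the closed-form magnitude response to 1e-6. Zero-phase
  filtering runs each cascade forward and backward with odd-reflection
  padding of three filter orders per edge; the first and last 10 s of a
  recording are excluded from analysis windows instead of fighting the
  low-frequency edge transient.
- **Delineation.** QRS detection is an energy-envelope detector with a
  250 ms refractory period; T landmarks use the tangent method against a
  per-beat isoelectric level estimated as the median of the beat's RR
  interval (the zero-phase high-pass shifts the baseline away from zero,
  and ignoring that shift biases tangent crossings by tens of
  milliseconds). Tangent intersections give sub-sample resolution.
- **Warping grid.** 0.5 ms on the reference support; a Sakoe-Chiba band
  of 25% of the grid bounds the search (after time normalisation the
  optimal path is near-diagonal; `band = 1` disables the constraint and
  is used when validating against exhaustive path enumeration). Cost ties
  resolve to the earliest-listed step, the diagonal.
- **Ties in MWTW initialisation.** The initial template is the wave of
  median duration with a deterministic, order-invariant tie-break
  (duration distance, then duration, then amplitude sums).
- **NNLS.** The active-set solver is deterministic; no seeds are involved
  in model fitting.
- **Reference pairing.** The reference MWTW is the valid window nearest
  the dialysis-end hour (ties to the earlier window), and each blood hour
  is paired with its nearest valid window under the same rule.

## Problem sizes in tests

The test and validation runs synthesise sessions of 12 minutes to 1.2
hours at 200-500 Hz with window grids densified to every 10 minutes,
window-level wave caps of 15-30 beats, and blood-sample hours placed at
window centres. These sizes were chosen so the full chain — generation,
filtering, lead transformation, delineation, windowing, warped averaging,
marker extraction, model fitting — runs in minutes while every stage still
operates above its minimum-data thresholds; the generator's defaults keep
the full-scale study protocol. Cohort-level validation uses 100-200
marker-level patients.

## Known limitations

- The warping-marker reconstruction (SRSF + dynamic programming, the sign
  convention, the sqrt-RR correction) follows the published framework of
  the marker family but is not a bit-exact reimplementation of any
  specific prior codebase; it is validated against closed forms and
  exhaustive search instead.
- The delineator satisfies the stated contract (sensitivity, ordering,
  tangent landmarks) on the generator's beat family; it is not a
  general-purpose clinical delineator.
- Absolute [K+] is out of scope: only variations relative to the
  dialysis-end sample are modelled, so every deployment needs the h4
  anchor.
- Model transfer across sessions (learning at one dialysis session,
  predicting at a later one) is not implemented.
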