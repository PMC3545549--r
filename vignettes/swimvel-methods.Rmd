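---
title: "Estimating front-crawl velocity from a single sacrum-worn IMU"
author: "swimvel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating front-crawl velocity from a single sacrum-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimvel)
```

## The problem

Velocity is the most direct measure of swimming performance, but measuring it
in water is awkward: video digitization is slow and fragile, and tethered
speedometers — a cord paid out from a poolside pulley — are accurate but
constrain the swimmer. A single waterproof inertial measurement unit (IMU,
3-D accelerometer + 3-D gyroscope) worn on the sacrum is unobtrusive, but
integrating its signals drifts: gyroscope errors tilt the estimated
orientation, gravity then leaks into the estimated forward acceleration, and
a double dose of drift lands in the integrated velocity.

`swimvel` implements a drift-controlled estimation chain for 25 m front-crawl
trials that start from a motionless posture in water:

1. **Initial pose.** Over a static start window the accelerometer reads the
   reaction to gravity, with magnitude `g`. The initial quaternion rotates the
   normalized reading onto the global vertical through the smallest angle
   about a horizontal axis. The start azimuth is taken as zero: without a
   magnetometer the forward direction is *defined* by the start pose, and held
   by the roll constraint below.
2. **Strapdown integration.** The sensor-to-pool quaternion is advanced each
   sample by the axis–angle increment of the gyroscope rate (angle
   `|omega|/f`), composed on the sensor side (the gyroscope measures body
   rates), and renormalized every step.
3. **Roll-constraint drift correction.** In front crawl the sacrum rolls, on
   average, about the swimming direction. Per stroke cycle, the first
   principal component of the pool-frame angular velocity should therefore be
   the forward axis; its deviation is attributed to gyroscopic drift and
   removed by a corrective rotation that ramps linearly from zero at the
   cycle start to the full measured angle at the cycle end.
4. **Forward acceleration and velocity.** The accelerometer is rotated into
   the pool frame with the corrected orientation, gravity removed, the
   forward component taken, and trapezoidally integrated from rest.
5. **Velocity de-drifting.** The forward acceleration is segmented into
   regimes by a geometric-moving-average (GMA) variance change detector.
   Within each segment, per-cycle velocity maxima and minima are
   interpolated by shape-preserving (non-overshooting) piecewise cubics; the
   midline of the two envelopes tracks drift plus the (quasi-constant)
   regime level. The *within-segment variation* of the midline, stitched
   continuously across segment boundaries, is subtracted, and the result is
   anchored so that the trial mean equals pool length / trial duration.

The estimate is evaluated against a tethered-reference model (cord length
from an elevated pulley, parallax-corrected) with the field's agreement
statistics: cycle-mean bias and precision, Bland–Altman limits of agreement
with a heteroscedasticity screen, Spearman rank correlation, the normalized
pairwise variability index (nPVI), instantaneous RMS/max errors, and the
intra-cyclic velocity variation (IVV).

## Conventions that matter

* Quaternions are Hamilton, scalar-first; `q` maps sensor to global frame and
  acts on vectors by `q v q*`. Rotations are active and right-handed.
* The global frame has Y along the swimming direction, Z up.
* The accelerometer reading is specific force: at rest an upright sensor
  reads `c(0, 0, +9.81)`. The initial inclination is
  `acos(a0_hat . Z)` of the *normalized* reading under this convention, so an
  upright sensor gives zero inclination.
* The corrective axis for a principal axis `p` is `p x [0,1,0]`: with the
  active-rotation convention this is the sign for which rotating `p` by the
  drift angle lands exactly on the forward axis.
* Corrections compound across cycles: each cycle's principal axis is measured
  with all previous corrections applied, so the measured angle is the drift
  accrued *within* that cycle — which is what the linear in-cycle ramp
  assumes. Without compounding, the correction would reset at every cycle
  start and leave a sawtooth residual equal to the whole accumulated drift.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| IMU rate `f` | 500 | Hz | the target recording hardware |
| reference rate `f_ref` | 100 | Hz | tethered-speedometer hardware; comparisons run at this rate |
| pulley height | 0.72 | m | geometry of the reference installation |
| gravity | 9.81 | m s^-2 | configurable for local gravity |
| GMA threshold | 0.20 | fraction of var(a) | smaller splits spuriously, larger misses regime changes |
| GMA lambda | 0.999 | — | ~2 s memory at 500 Hz; see below |
| cycle low-pass | 3 | Hz | isolates body roll from limb dynamics |
| cycle refractory | 0.4 | s | physiological floor of a stroke-cycle period |
| static window | 0.5 | s | initial-pose averaging; validated by accel-norm SD < 0.05 g and mean rate < 0.1 rad/s |
| `smooth_cycles` | 1 | cycles | optional running median over the drift trajectory |

The GMA forgetting factor deserves a note: with an exponentially weighted
variance the intra-cycle acceleration oscillation leaks into the estimate
when the memory is much shorter than a cycle. At 0.4 s memory the running
variance of a realistic swim signal fluctuates by more than the 20%
detection threshold, splitting steady swimming into spurious segments; at
about 2 s (one to two cycles) the leakage is ~5x smaller while a variance
step is still localized within ~200 samples. The recursion is seeded from
its first warm-up window (a cold start from zero would itself look like a
change), and adjacent segments whose sample variances differ by less than
the detection threshold are merged afterwards: a segment boundary is only
meaningful if the variance actually changed regime.

## Numerical choices

* **Shape-preserving envelopes.** Envelope interpolation uses the
  Fritsch–Carlson monotone piecewise cubic (`pracma::pchip`), which cannot
  overshoot its knots; with only two knots it degrades to linear. Query
  points are clamped to the knot range, i.e. envelopes extend as constants.
* **Drift stitching.** Integration drift is continuous in time, while level
  steps between swimming regimes are real signal. The subtracted drift is
  therefore the midline's variation within each segment, with offsets chosen
  to keep the drift curve continuous at segment boundaries. Segments with
  fewer than two whole cycles (typically the push-off) fall back to a
  constant, i.e. contribute no drift — accepting that drift accrued before
  the first envelope knot is unobservable to this method.
* **Mean anchoring** is additive (integration drift is additive in
  velocity), and exact: the trial mean of the output equals
  pool length / duration to machine precision.
* **Zero-phase filtering.** All low-pass steps (cycle detection, anti-alias
  before decimation) use a Butterworth filter run forward and backward, with
  the series extended by edge reflection first — `signal::filtfilt` alone
  leaves large end transients.
* **Cycle detection hysteresis.** Cycle boundaries are upward zero crossings
  of the filtered roll rate, with a 0.4 s refractory period, and a crossing
  only counts if real rolling (>= 10% of the robust roll amplitude) follows
  it; filter ringing around the push-off onset would otherwise create
  micro-cycles.
* **Alignment.** Estimate and reference are aligned by maximizing the
  cross-correlation with *per-overlap* normalization; the fixed-denominator
  estimator (`stats::ccf`) is biased toward small lags and can misplace a
  flat peak by several samples.
* **Degenerate inputs.** A static reading far from `g` in norm, a rolling
  start, fewer than two detected cycles, or a cord length below the pulley
  height all raise errors naming the stage; a cycle whose angular-velocity
  cloud is degenerate is skipped with a warning and inherits the previous
  correction.

## The synthetic swimmer

No recorded data ship with the package; every stage is validated against a
simulator (`simulate_swim()`) that emulates the study conditions: a
motionless hold (1 s), a smooth push-off ramp (2 s), then steady swimming at
a per-regime mean velocity; intra-cycle velocity oscillation mainly at twice
the body-roll rate (two arm pulls per roll cycle, fraction 0.7) plus a
component at the roll rate itself (0.3); sacral roll of 0.6 rad amplitude;
slow random pitch/yaw wobble (low-passed white noise, 2 degrees RMS);
constant sensor biases and white noise (gyro 0.5 deg/s bias and noise SD,
accelerometer 0.02 m s^-2 bias, 0.05 m s^-2 noise SD — MEMS-class values); a
constant 0.1 rad mounting tilt; and a cord-length reference sampled at
100 Hz from a pulley 0.72 m above water, 0.5 m behind the start position.
The gyroscope signal is generated as the exact per-sample orientation
increment scaled to a rate (a standard discretization of body rates), so
that with imperfections zeroed the strapdown stage reproduces the truth
exactly and any error seen in noisy runs is attributable to the sensor
model, not to numerics.

Presets (`default_scenarios()`) mirror a four-trial incremental protocol at
70–100% of a typical best-100 m velocity for an elite group (1.68 m/s,
intra-cycle amplitude 0.14) and a recreational group (1.34 m/s, amplitude
0.20), with stroke rates rising with speed within 0.5–1 Hz.

What the simulator does *not* model: stroke-locked (periodic) pitch/yaw
undulation, hydrodynamic force structure, swimsuit attachment artifacts,
turns and dives, colored sensor noise, temperature-dependent bias ramps.
Passing the recovery tests therefore shows the chain is correct under its
own assumptions and realistic sensor errors; it does not certify field
accuracy, which the original validation against a tethered reference on real
swimmers addresses.

## Known limitations

* **Forward-axis twist is unobservable.** The roll constraint cannot see
  rotation error about the swimming direction, and gyro bias generally has a
  component along it. That twist is harmless for forward velocity (the
  forward projection is invariant under it) but it bounds how much the
  *total* terminal orientation error can shrink: on the default preset the
  correction removes ~77% of the tilt while the total-angle error improves
  far less. Diagnostics expose per-cycle drift angles so the split is
  visible.
* **Constraint noise.** Real pitch/yaw motion tilts a single cycle's
  principal axis off the forward direction by a degree or two; the per-cycle
  correction converts that into orientation noise. With the wobble modelled
  here, cycle-mean precision on a single trial is typically 3–7 cm/s but the
  draw matters; with an oracle orientation the rest of the chain achieves
  ~2.5 cm/s. An optional running median over the accumulated drift
  trajectory (`smooth_cycles`) is available but does not help when the
  wobble is correlated across neighboring cycles, which is why it is off by
  default.
* **Drift before the first envelope knot** (hold and push-off ramp) is
  unobservable to the de-drifting stage and is absorbed only by the global
  mean anchor.
* The trial mean velocity must be known (pool length and duration); the
  method is per-lap, not real time.

## Problem sizes used in the test suite

Simulated trials are 25 m at 500 Hz (roughly 8,000–11,000 samples,
14–18 stroke cycles); statistical oracles run on sequences of 10–100
elements; GMA checks use 10,000-sample seeded noise. The whole suite and the
acceptance script each run in well under a minute on one core.
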