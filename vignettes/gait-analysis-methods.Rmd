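---
title: "Methods: gait parameters and interlimb coordination from quaternion sensor streams"
author: "gaitq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gait parameters and interlimb coordination from quaternion sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitq)
```

`gaitq` analyses walking trials recorded by ten body-worn orientation
sensors. This vignette documents the model behind each stage, the tunable
parameters and their defaults, the design choices made where the design was
genuinely open, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Coordinate conventions and the quaternion layer

Quaternions are scalar-first `(w, x, y, z)`, the order in which the sensors
emit them, and all comparisons respect the double cover (q and −q are the
same rotation). The world frame is right-handed with **x forward** (the
walking direction), **y up**, and **z lateral** to the subject's right.
Every limb segment rests pointing straight down, direction `(0, −1, 0)`,
with a starting angle of zero; this makes the sensors' local-orientation
mode (each sensor measures relative to its power-on pose) literal: a
subject who stands still at power-on has all segments at identity.

The *sagittal angle* of a segment is the signed angle, in degrees, between
the projection of its world direction onto the x–y plane and the rest
direction, positive forward. It is the signal the event detector consumes.
The projection degenerates when a segment points (near-)laterally; the
angle is then reported as `NA` rather than an arbitrary value. Rotations
about the vertical axis leave a downward segment downward, so they read as
0°, not as `NA`.

## Body model

The skeleton is a ball-and-stick model: ten segments (upper/front arm ×2,
thigh/shank/foot ×2) with fixed lengths, rooted at static shoulder and hip
positions. Default lengths (upper arm 0.30 m, front arm 0.28 m, thigh
0.42 m, shank 0.42 m, foot 0.25 m) are ordinary adult proportions and are
configuration, not measurement; all of them are overridable in
`skeleton_config()`.

Each segment is oriented by **its own sensor's absolute orientation** — no
parent-to-child composition — and limbs are chained by translation,
proximal to distal. This mirrors how the acquisition system combines
segments: both segments of an arm start at the origin, are rotated
independently, and the distal one is translated to the end of the proximal
one. Consequently a limb can only be reconstructed when *all* of its
segments arrived that frame; a missing segment invalidates exactly its own
limb and no other.

Two angle signals are exposed for event detection: the sagittal angle of
the shank (default) and the knee flexion angle between thigh and shank
directions. Both conventions appear in practice; the shank signal is the
default because it is what the reference trials measured, and the choice is
a config switch (`mode`) rather than a hard-coded assumption.

## Recording format and packet stream

A recording is a timestamped n×40 matrix: 40 columns of quaternion
components, four per sensor in sensor-ID order 0–9, plus a per-sensor
presence mask. At the 59 Hz system rate a gap-free 10 s trial is exactly
590 rows. Packets (`timestamp, sensor_id, w, x, y, z`) are binned onto a
regular 1/rate grid anchored at the first timestamp; a sensor missing from
a bin is masked, and a duplicate within a bin resolves last-write-wins.
Because every sample carries its own timestamp, lost packets degrade the
recording gracefully instead of corrupting alignment.

The file format is plain text: `# key=value` header lines, then one row
per frame with the timestamp and the 40 components at exactly four decimal
places (the acquisition system's storage precision), `NA` for missing
cells. Round-tripping a recording through the format is lossless at that
precision, and re-writing a read file reproduces it byte for byte.
Timestamps are receiver-side seconds from trial start.

## Event detection

Heel contact is declared at each maximum of the monitored leg angle,
toe-off at each minimum. Only the *timing* of these extrema enters the
gait parameters (except the heel-contact angle used by stride length), so
constant calibration offsets in the angle do not affect the timing
results.

The detector pipeline is:

1. **Gap interpolation.** Frames lost to packet drop are linearly
   interpolated (ends extended with the nearest value).
2. **Smoothing.** A centred moving average, default window 0.15 s. Sensor
   noise of a few degrees otherwise produces spurious local extrema whose
   topographic prominence exceeds any reasonable threshold.
3. **Extrema detection** (`find_peaks`): local maxima (plateaus count once,
   at the earliest index), filtered by prominence (default 5°) and minimum
   separation (default 0.4 s, below any plausible stride period; when two
   candidates collide the higher wins, ties to the earlier). With both
   filters disabled the detector reduces *exactly* to a brute-force scan
   for samples greater than both neighbours — that equivalence is
   property-tested.
4. **Sub-sample refinement.** The gait angle cycle is asymmetric around
   its extrema (the rising and falling limbs have different slopes), so
   both a moving-average extremum and a raw argmax under noise are biased
   toward the shallower side — enough (~0.02 s/event) to visibly deflate
   double support, whose intervals are only ~0.15 s long. Each detected
   extremum is therefore refined by a least-squares parabola over the
   smoothing window on the *unsmoothed* series; the vertex provides an
   (unbiased under i.i.d. noise) sub-sample event time and a low-noise
   estimate of the angle at the event, which stride length uses.

A leg with fewer than two detected heel contacts raises an
insufficient-cycles error: no gait cycle exists to analyse.

## The five parameters

With `H` heel-contact times, `T` toe-off times, `n` peak counts and
`T_total` the trial duration:

* **Double support** = Σ_{i=1}^{n−1} (T(i) − H(i)) / T_total, where each
  heel contact is paired with the first *opposite-leg* toe-off after it and
  the pairings of both legs are pooled (a per-leg breakdown is available).
  The sum deliberately stops at n−1: trailing contacts without a following
  cycle are excluded, so the estimate is biased slightly low on short
  trials — visible in the worked examples, and one reason the package
  defaults to 30 s trials for quantitative recovery work.
* **Stride length** = l·sin θ(i+1) + l·sin θ(i) per cycle, mean over the
  cycles of both legs, in cm. θ(i) is the monitored segment's sagittal
  angle *at* heel contact i — the only dimensionally meaningful reading of
  the formula, whose printed form takes the sine of a time. Angles of 90°
  or more trigger an implausible-angle warning.
* **Gait speed** = d / T_total, converted to m/min; d is user-supplied.
* **Cadence**: three estimators. `"rate"` (default) divides the pooled
  heel-contact count minus one by the span between first and last contact;
  it is exact on periodic gait regardless of where the trial window cuts
  the cycle. `"count"` divides the raw step count by the trial duration —
  simpler, but biased by up to one step per trial window. `"strides"`
  halves the peak count (the stride-counting convention) and reports
  strides/min. The count-based estimators are retained because they are
  what simpler systems report; their window bias (~1–6 steps/min at 10 s)
  is the likely explanation for count-derived cadences reading a few
  percent low.
* **Swing phase** = H(i+1) − T(i) per cycle, using the *same* leg's
  toe-off within the cycle; reported as seconds and, primarily, as the
  fraction of the cycle duration H(i+1) − H(i). A formula of bare seconds
  cannot be compared across cadences, which is why the dimensionless
  fraction is primary. Cycles without a toe-off are skipped with a
  warning.

All parameters are deterministic given a recording and configuration.

## Interlimb coordination

Coordination is the lag-maximised Pearson correlation between two segment
angle waveforms: both series are linearly detrended and mean-removed, and
the coefficient is the maximum over integer-sample lags up to ±`max_lag`
(default 1.5 s, about one gait cycle). Lag maximisation makes the measure
invariant to the fixed phase offsets between limbs (left/right legs are in
antiphase; arms counter-swing); a zero-lag mode (`max_lag = 0`) is
available. Whole-series detrending slightly depresses the coefficient of a
finite, truncated waveform (≈10⁻³ at 30 s) — an accepted end effect.

`compare_trials()` contrasts the within-trial pair coefficients with
pairings of one trial's segments against the other's (trials truncated to
common length), summarised by median and quartiles per group, suitable for
a box plot (`plot()` method). Which segment pairs belong in each group is
not canonical; all unordered pairs are pooled by default.

## The synthetic gait generator

The simulator replaces the sensor hardware for validation. Its kinematic
model is built for *analytic ground truth*, not biomechanical fidelity:

* Each leg follows a **phase-warped cosine** of the gait phase: a
  piecewise-linear bijection of the cycle phase places the maximum (heel
  contact) at phase 0 and the minimum (toe-off) at 2π·(1 − swing), so the
  configured swing fraction is honoured while event times stay closed-form.
  A cosine plus one harmonic cannot do this: its extrema sit at fixed
  phases regardless of coefficients.
* The shank amplitude A is chosen so the stride-length formula inverts
  exactly: 2·l·sin A = stride length at heel contact. Thigh and foot are
  scaled copies (0.6 and 0.8) of the same cycle; arms counter-swing in
  antiphase to the ipsilateral leg (amplitude `arm_swing`, default 15°)
  when phase-locked.
* Legs are in exact antiphase, and the double-support fraction is the
  gait-cycle identity 1 − 2·swing; the parameters accept both fractions
  but reject inconsistent combinations rather than silently honouring one.
* **Cycle-to-cycle variability**: the gait phase carries a random-walk
  jitter (default 0.15 rad/√s ≈ 3% stride-time variability, typical of
  healthy adults). All segments of a trial share the jittered clock, so
  interlimb locking is preserved within a trial while two independently
  generated trials decorrelate — without it, two strictly periodic trials
  at the same cadence would be indistinguishable from phase-locked limbs
  after lag alignment. Ground-truth event times are solved from the
  realised phase path (exact for a linear phase, and verified to match the
  closed form when jitter is zero); ground-truth cadence, speed and
  distance are likewise the realised values of the trial.
* Sensor noise is Gaussian in angle space (before quaternion conversion,
  keeping unit norm exact; default 1°), and packet loss is i.i.d. Bernoulli
  per packet (default 2%) — the observable consequence of radio
  contention, not a mechanistic model of it.
* Angles convert to quaternions as rotations about the lateral axis, the
  flexion/extension axis; sensors are taken to be calibrated at the rest
  pose before the walk, so the walk itself starts mid-cycle (initial phase
  π/3, placing the first events inside the trial).

Defaults (cadence 80 steps/min, stride 1.2 m, leg length 0.9 m, swing 0.4,
10 s at 59 Hz) are ordinary self-selected walking values. Everything is
driven by one integer seed; identical parameters give byte-identical
recordings.

**What passing tests on this generator do and do not show.** The generator
exercises the whole pipeline — packet assembly, masking, angle extraction,
event detection, parameter formulas, coordination — under controlled,
recoverable conditions. It does not emulate soft-tissue artefact, strap
slippage, sensor-axis miscalibration, asymmetric or pathological gait,
non-sagittal motion, or bursty (non-independent) packet loss; recovery
accuracy on synthetic trials is therefore an upper bound on, not an
estimate of, accuracy on real recordings.

## Numerical choices and problem sizes

* Quaternions are validated to unit norm within 1e-6 before rotation;
  vector norms are preserved to 1e-9; packet quaternions may deviate from
  unit norm by up to 0.02 (sensor noise allowance) and are normalised on
  ingest.
* Plateau extrema tie-break to the earliest index; separation conflicts
  keep the higher extremum.
* The degenerate sagittal projection threshold is 1e-8 on the projected
  length.
* Quantitative recovery checks use 30 s trials and 20 seeds: long enough
  that the n−1 truncation of the double-support sum and the ±1-step window
  effects are small against the tolerances, while keeping the full suite
  fast. Coordination comparisons use 20–30 s trials and 10 seeds, with the
  second trial's cadence varied over 72–88 steps/min (different walks
  realistically differ in rate).
* A residual event-timing bias of ~0.01 s survives the parabola
  refinement, traceable to the sampling grid aliasing against the kinked
  waveform; it is visible mainly in double support (intervals of ~0.15 s)
  and is accepted rather than corrected, since any correction would encode
  knowledge of the synthetic waveform that a hardware-independent analyser
  cannot have.

## Known limitations

* The analyser and simulator share one axis convention; ingesting real
  sensor hardware would need a calibration mapping from that sensor's
  quaternion frame, which the package does not provide.
* Stride length assumes sagittal-plane geometry and a user-measured leg
  length; it degrades with out-of-plane motion.
* Double support as defined (opposite toe-off after heel contact, n−1
  pairs) underestimates on short trials; report durations alongside
  fractions.
* The event model equates heel contact/toe-off with angle extrema; gaits
  where that correspondence breaks (severe shuffling, toe-walking) will
  mis-time events no matter how well the extrema are found.
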