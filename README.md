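# gaitq

Gait analysis and interlimb coordination from wearable quaternion sensor
streams.

`gaitq` is a hardware-independent reimplementation of the analysis pipeline
of a full-body wireless motion-tracking system: ten orientation sensors
(front arms, upper arms, thighs, shanks, feet) stream unit quaternions at
59 Hz to a receiver, which assembles them into a timestamped n×40 recording
matrix, reconstructs a segment-based 3D human model, detects gait events
from joint-angle extrema, and reports spatiotemporal gait parameters and
interlimb coordination. The package is aimed at researchers in wearable
biomechanics who want to analyse (or prototype against) such recordings
without the physical sensor network: a seeded kinematic simulator generates
realistic ten-sensor walking trials with analytic ground truth.

## The model

Each sensor reports its absolute orientation as a unit quaternion
(w, x, y, z). Limb segments have fixed lengths and rest direction
(0, −1, 0) ("pointing down"); a segment's world direction is the rest
direction rotated by its own sensor's quaternion, and limbs are chained by
translation (elbow = shoulder + L·R(q_upper)·d, wrist = elbow +
L·R(q_fore)·d, and hip → knee → ankle → toe analogously). A limb with any
missing segment that frame is invalid and is not reconstructed.

Gait events come from the sagittal-plane angle θ(t) of a leg segment
(shank by default): **initial heel contact** at each maximum of θ,
**toe-off** at each minimum. With H the heel-contact times, T the paired
opposite-leg toe-off times, n the number of peaks, and T_total the trial
duration, the five reported parameters are

- double support = Σ_{i=1}^{n−1} (T(i) − H(i)) / T_total,
- stride length = l·sin θ(H(i+1)) + l·sin θ(H(i)) per cycle (mean, in cm),
  with l the subject's leg length,
- gait speed = d / T_total (m/min), with d the walked distance,
- cadence in steps/min from the detected heel contacts,
- swing phase = H(i+1) − T(i) per cycle using the same leg's toe-off,
  reported both in seconds and as a fraction of the gait cycle.

Interlimb coordination is quantified by the lag-maximised Pearson
cross-correlation between segment angle waveforms; within one trial the
limbs are phase-locked and the coefficients approach 1, while waveforms
from different trials decorrelate.

## Worked example

```r
library(gaitq)

p <- gait_sim_params(cadence = 80, stride_length = 1.2, duration = 30,
                     noise_sd = 3, packet_loss = 0.02, seed = 42)
trial <- simulate_trial(p)
trial$recording
#> <gait_recording> 1770 frames x 40 columns, 59.0 Hz, 29.98 s
#>   present cells: 98.0%  subject='simulated' trial='seed42'

report <- gait_report(trial$recording,
                      subject_params(leg_length = 0.9,
                                     distance = trial$truth$distance))
report
#> <gait_report>
#>   Stride length     119.7 cm
#>   Gait speed         47.8 m/min
#>   Cadence            79.8 steps/min (rate)
#>   Double support    0.162 of trial
#>   Swing phase L     0.415 of cycle (0.63 s)
#>   Swing phase R     0.410 of cycle (0.62 s)
#>   [19+20 heel contacts over 30.0 s; shank_sagittal signal]
```

The simulated subject walked at 80 steps/min with a 1.2 m stride, 40% swing
phase and 20% double support; despite 3° sensor noise and 2% packet loss
the report recovers cadence and stride closely. (Double support reads low
by construction: the formula sums only the first n−1 event pairs, so edge
cycles of a finite trial are excluded.) Coordination between two different
walks separates cleanly from the within-trial coupling:

```r
other <- simulate_trial(gait_sim_params(duration = 30, cadence = 75, seed = 43))
compare_trials(trial$recording, other$recording)
#> <trial_comparison>
#>        group  n        q1    median        q3
#>  cross-trial 45 0.1054031 0.1122733 0.1171996
#>   same-trial 45 0.9288395 0.9490494 0.9722196
```

A command-line interface wrapping the same pipeline lives at
`inst/cli/gaitq.R`:

```sh
Rscript inst/cli/gaitq.R simulate --duration 10 --seed 1 --out trial.rec
Rscript inst/cli/gaitq.R analyze --in trial.rec --leg-length 0.9 --distance 8
Rscript inst/cli/gaitq.R coordinate --in a.rec --in2 b.rec --out pairs.tsv
Rscript inst/cli/gaitq.R export-pose --in trial.rec --out pose.tsv
```

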