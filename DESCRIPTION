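Package: gaitq
Title: Gait Analysis and Interlimb Coordination from Wearable Quaternion
    Sensor Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-independent analysis of full-body wearable motion
    recordings made with ten body-worn orientation sensors (front arms,
    upper arms, thighs, shanks, feet). Parses timestamped quaternion packet
    streams, assembles them into n-by-40 recording matrices, reconstructs a
    segment-based 3D human model by forward chaining of fixed-length limb
    segments, detects heel-contact and toe-off events from joint-angle
    extrema, and computes five spatiotemporal gait parameters (stride
    length, gait speed, cadence, double support, swing phase) together with
    interlimb coordination via lag-maximised cross-correlation of angle
    waveforms. A seeded kinematic simulator generates realistic 59 Hz
    ten-sensor walking trials with analytic ground truth, replacing the
    physical sensor hardware for validation and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
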