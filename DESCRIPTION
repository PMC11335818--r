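Package: headgaze
Title: Eye-Head Gaze Shift Measurement with a Wearable Eye Tracker and a
    Ceiling Camera
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to measure large horizontal eye-head gaze shifts from a
    wearable eye tracker combined with a downward-looking ceiling camera
    that tracks a planar fiducial marker on the participant's head.
    Recovers head yaw from marker corner pixels via planar
    perspective-n-point (homography decomposition), converts eye-tracker
    scene-camera pixels to eye-in-head angles, synchronizes and fuses both
    streams into world-fixed gaze G = E + H + c, quantifies data quality
    (accuracy, windowed RMS sample-to-sample precision, effective
    frequency, sample-interval distribution), and segments combined gaze
    shifts into saccade and vestibulo-ocular reflex phases with eye-head
    coordination summaries. A kinematic simulator generates ground-truth
    recordings of the full protocol so every pipeline stage is testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
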