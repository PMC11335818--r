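# headgaze

Measurement and simulation of **large horizontal eye–head gaze shifts**
from a wearable eye tracker combined with a fixed, downward-looking camera
that tracks a square fiducial marker on the participant's head.

When people look between targets far apart (up to ~140° of visual angle),
the eyes alone cannot get there: the oculomotor range is about ±40°, so the
head carries the remainder while the vestibulo-ocular reflex (VOR)
counter-rotates the eyes to stabilize gaze outside the saccade. Measuring
such gaze shifts needs two streams:

* **E** — eye-in-head azimuth, from the eye tracker's gaze point in
  scene-camera pixels;
* **H** — head-in-world yaw, from the pose of a planar marker seen by the
  ceiling camera.

World-fixed gaze is their sum plus a calibration constant:

```
G(t) = E(t) + H(t) + c
```

with *c* fit by least squares against wall targets of known azimuth (it
absorbs the scene-camera mounting offset and sets the gaze zero in the
corner of the room). Angles are degrees, positive leftward.

## What the package does

| stage | functions |
|---|---|
| planar marker pose (perspective-n-point via homography decomposition) | `project_marker()`, `estimate_planar_pose()`, `estimate_head_pose_series()`, `pose_to_head_yaw()` |
| scene-camera pixels → eye-in-head angles (tangent mapping) | `pixels_to_angles()`, `angles_to_pixels()` |
| clock sync on head-shake episodes, resampling, fusion, calibration | `synchronize()`, `resample_to_rate()`, `fuse()`, `calibrate_constant()`, `gaze_pipeline()` |
| data quality: accuracy, windowed RMS sample-to-sample precision, effective frequency, sample-interval modes | `accuracy()`, `rms_s2s_precision()`, `effective_frequency()`, `interval_distribution()`, `quality_report()` |
| gaze-shift segmentation (saccade + VOR phases) and eye-head coordination | `detect_gaze_saccades()`, `vor_phase()`, `pre_post_velocities()`, `classify_head_lead()`, `coordination_summary()` |
| ground-truth kinematic simulator of the full protocol | `sim_config()`, `simulate_gaze_shift()`, `simulate_oscillation()`, `simulate_session()`, `truth_eval()` |
| file I/O and a command-line interface | `read_*`/`write_*`, `headgaze_cli()` |

The simulator is first-class: it generates a complete synthetic recording —
calibration sweep over 12 wall targets (23 fixations), head-oscillation
synchronization episodes, six target-separation conditions from 17.6° to
143.6° with alternating self-paced shifts, marker corners rendered through
the ceiling-camera pinhole model, eye samples with the bimodal 4/8-ms
interval mixture at a 200.54-Hz effective rate, a true clock offset between
streams, and Gaussian angle noise — together with exact ground truth, so
every pipeline stage has an oracle.

## Worked example

Simulate a two-condition session and run the full pipeline:

```r
library(headgaze)

cfg <- sim_config(target_separations = c(38.3, 118.9),
                  shifts_per_condition = 5, seed = 1L)
ses <- simulate_session(cfg)

res <- gaze_pipeline(ses$markers, ses$eye, ses$targets,
                     ses$truth$ceiling_camera, ses$truth$scene_camera,
                     ses$truth$marker,
                     sync_segments = ses$truth$oscillation_windows,
                     reference_window = ses$truth$reference_window)

res$sync_offset_s        # recovered clock offset
res$calibration          # fitted constant c
ang <- res$eye_angles; poses <- res$pose_series
quality_report(res$record,
               sampled_signal(ang$timestamp, ang$azimuth_deg, ang$valid),
               sampled_signal(poses$timestamp, poses$yaw_deg, poses$valid),
               ses$targets[, c("t0", "t1")], ses$targets$azimuth_deg)
ev <- detect_gaze_saccades(res$record,
                           condition_windows = ses$truth$condition_windows)
coordination_summary(ev)
```

Output (seed 1):

```
sync offset: 0.2000 s (true 0.2000)
<calibration_result> c = 1.202 deg, MAE = 0.004 deg over 7 windows
<quality_report>
  accuracy (mean abs): 0.004 deg
  precision RMS-S2S:   E 0.0760  H 0.0351  G 0.0590 deg
  effective frequency: 200.54 Hz
  interval mode 1: 4.00 ms (sd 0.079 ms, weight 0.75)
  interval mode 2: 8.00 ms (sd 0.079 ms, weight 0.25)
<coordination_summary> 10 events, 2 conditions
  head velocity slope: 2.331 1/s (se 0.003)
  head leads fraction: 1.00
  saccade amplitude sublinear in gaze amplitude: TRUE
  condition n gaze_amplitude_deg ... peak_head_velocity_dps
1      38.3 5               37.6 ...                   88.3
2     118.9 5              118.3 ...                  275.4
```

Reading it: the clock offset (0.2 s) and the calibration constant
(c = 1.2°) are recovered to sub-millisecond / hundredth-degree accuracy;
the eye stream's RMS-S2S precision (0.076°) reflects the injected 0.05°
sample noise (x sqrt(2) for successive differences, slightly inflated by
head-motion windows); the effective frequency matches the 200.54-Hz
target; every shift is head-led (the head starts 80 ms before the
saccade); peak head velocity rises with gaze amplitude at 2.33 1/s (the
configured slope is 2.31); and the saccade's share of the gaze shift
shrinks with amplitude (85% at 38.3°, 55% at 118.9°), the classic
sublinear main-sequence pattern for combined eye-head movements.

## Command line

Every stage is scriptable via `headgaze_cli()` (see `?headgaze_cli`), or
the wrapper installed at `system.file("cli", "headgaze", package =
"headgaze")`:

```sh
headgaze simulate --out sim --seed 7
headgaze pose     --markers sim/markers.csv --camera sim/ceiling_camera.json --out pose.csv
headgaze convert  --eye sim/eye.csv --camera sim/scene_camera.json --out angles.csv
headgaze sync     --eye-angles angles.csv --pose pose.csv --segments sim/oscillation_windows.csv --out sync.json
headgaze fuse     --eye-angles angles.csv --pose pose.csv --sync sync.json --targets sim/targets.csv --out fused.csv
headgaze report   --fused fused.csv --eye-angles angles.csv --pose pose.csv \
                  --targets sim/targets.csv --conditions sim/condition_windows.csv --out report.json
```

File schemas: marker corners
`timestamp,x0,y0,x1,y1,x2,y2,x3,y3,valid`; eye samples
`timestamp,x_px,y_px,valid`; targets `t0,t1,azimuth_deg`; fused record
`time,E_deg,H_deg,G_deg,dE_dps,dH_dps,dG_dps,valid`; camera models as JSON
`{width, height, focal_length_px, principal_point}`.

## Documentation

The methods vignette (`vignettes/headgaze-methods.Rmd`) describes the
measurement model, the detector and its thresholds, the simulator's
kinematic construction, and known limitations.
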