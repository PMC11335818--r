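---
title: "Measuring large eye-head gaze shifts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring large eye-head gaze shifts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headgaze)
```

## The measurement model

A wearable eye tracker reports where the eye points *relative to the head*
(E, the gaze point in scene-camera pixels), and a fixed, downward-looking
camera reports where the head points *relative to the room* (H, the yaw of
a planar fiducial marker worn on the head). Because both angles are
rotations about the same (vertical) axis, world-fixed gaze is their sum up
to a constant:

$$G(t) = E(t) + H(t) + c$$

All angles are in degrees with a single shared sign convention: positive is
a rotation toward the participant's left (counterclockwise seen from
above). The constant $c$ absorbs offsets that neither stream can see on its
own -- chiefly the mounting offset between the scene camera's optical axis
and the eye's straight-ahead -- and is fit against wall targets of known
azimuth, which places the gaze zero at the calibration corner.

The package assumes purely horizontal analysis (one rotational degree of
freedom), a room-scale setup in which head translation is negligible
(`translation_gaze_error(0.05, 2.45)` is about 1.2 degrees, the worst
case), and no parallax correction between the scene camera and the eye's
rotation centre.

## Head orientation from the marker

The marker is a square of known side length; its four corner pixels give a
homography to the marker plane, estimated by a direct linear transform on
intrinsics-normalized coordinates and decomposed into rotation plus metric
translation (first two rotation columns from the scaled homography columns,
third from their cross product, re-orthonormalized by the nearest rotation
under the Frobenius norm). No iterative reprojection refinement is applied:
at the marker image sizes of this setup (area near 90,000 px^2) the direct
solution's yaw error under half-pixel corner noise is well below 0.1
degree, which the test suite verifies by Monte-Carlo against the projection
oracle.

Head yaw H is the Z angle of the intrinsic Z-Y-X Euler decomposition, with
Z the camera optical axis. The source material names no Euler convention;
Z-Y-X with Z along the optical axis was chosen because the ceiling camera
looks straight down, so its optical axis coincides with the vertical axis
the task rotates about and the Z angle *is* the head angle. For pure-yaw
motion every sensible convention agrees; for combined rotations they would
not, which is documented rather than hidden. Frames whose marker image is
small (area below 1,500 px^2, where pose noise grows steeply) are flagged
invalid rather than dropped silently; downstream resampling bridges flagged
gaps shorter than 50 ms and marks longer ones invalid.

Lens distortion is not modelled (ideal pinhole): the long-focal machine-
vision lens of such setups is near-rectilinear, and the corner input may be
pre-undistorted upstream if needed.

## Eye orientation from scene pixels

Under the pinhole model a pixel maps to a visual direction by the tangent
relation `azimuth = atan((px - x) / f)` with
`f = (width / 2) / tan(fov_h / 2)`; for the 1088 x 1080 px, 82-degree
scene camera an edge pixel subtends exactly 41 degrees. The mapping is
exactly invertible (`angles_to_pixels()`), which the simulator exploits.
The vendor's own pixel-to-direction conversion is not public; the tangent
model is the one consistent with the stated resolution/field-of-view pair,
and within this package the simulator defines the forward model, so
round-trips are exact by construction. Eye timestamps are kept as received
(variable rate) until fusion.

## Synchronization, fusion, calibration

The two streams run on independent clocks. During the protocol's
head-oscillation episodes the participant fixates while shaking the head,
so eye velocity mirrors head velocity (dE = -dH); the offset is the lag
maximizing their normalized cross-correlation, refined to sub-sample
precision by parabolic interpolation of the peak. Velocities rather than
positions are correlated so drifts and constant offsets cancel. Episodes
come from annotations when available, otherwise from a sliding 2-s
energy detector on head velocity. A peak correlation below 0.5 raises an
error rather than returning a bogus offset. Timing precision scales with
oscillation frequency (the correlation peak of a slow sinusoid is flat);
at the simulator's default 2.5-Hz shake the offset is recovered to about
a tenth of a millisecond, at 1 Hz only to about a millisecond.

Both streams are then linearly interpolated onto a shared uniform 200-Hz
grid. Linear interpolation was chosen over polyphase filtering because the
eye stream's native timestamps are irregular (a bimodal 4/8-ms interval
mixture); it is exact for linear signals and leaves already-uniform input
unchanged. Grid points farther than 50 ms from any valid sample are marked
invalid, not extrapolated.

Calibration reduces to a one-parameter least-squares fit: each calibration
fixation is summarized by the median of the central 50% of its window
(robust to microsaccades and edge transients), and $c$ is the mean of
(target - median raw gaze). Per-target residuals and their mean absolute
value are reported; symmetric zero-mean residuals leave $c$ unchanged.

## Data quality

* **Accuracy** -- mean absolute difference between the median calibrated
  gaze per fixation window and the target azimuth.
* **Precision (RMS-S2S)** -- root-mean-square of successive sample
  differences per 41-sample window (205 ms at 200 Hz, n x dt bookkeeping),
  window slid by one sample, median across windows. The median makes the
  metric robust to the minority of windows spanning saccades, so no
  fixation classification is needed; windows containing invalid samples
  are skipped. For iid noise of standard deviation sigma the statistic
  converges to sigma * sqrt(2). Precision of the raw eye and head streams
  is computed *before* resampling: interpolation onto the grid attenuates
  sample-to-sample noise by roughly 20%, which would misstate the sensor.
* **Effective frequency** -- valid samples divided by the first-to-last
  time span; the data-loss summary of choice for a tracker that never
  flags invalid samples itself.
* **Interval distribution** -- successive timestamp differences clustered
  by 1-D two-means, collapsing to one mode when the centers are not
  separated beyond the pooled spread. The eye tracker's distribution is
  bimodal around 4 and 8 ms (an 8-ms interval is one dropped frame).

## Gaze-shift segmentation

No detection algorithm is prescribed by the source material, so the
detector is a design decision, chosen for the structure of combined
eye-head shifts: outside saccades the VOR holds gaze velocity near zero
even while the head moves fast, so thresholding *gaze* velocity isolates
the saccadic phase cleanly.

| parameter | default | why |
|---|---|---|
| detection threshold | 50 deg/s | far above the noise floor (~2 deg/s smoothed) and below the slowest shift peaks (~350 deg/s) |
| minimum supra-threshold duration | 3 samples | rejects single-sample noise spikes riding on slow gaze movements |
| boundary refinement | 10% of the event's peak, sub-sample interpolated | scale-free landmark; interpolation removes half-sample quantization |
| merge gap | 50 ms | glissade-like double crossings belong to one event |
| minimum amplitude | 5 deg | protocol shifts are 17.6 deg and larger |
| velocity estimator | 5-sample local-quadratic smoother + central difference | exact for locally quadratic signals, so bell-shaped profiles are not biased |

The VOR phase runs from the saccade offset until head velocity falls below
10 deg/s; its gain is the ratio of mean eye to mean head velocity,
estimated from 20 ms after the detected offset onward. The settle period
matters: the 10%-of-peak offset precedes the true saccade end, and VOR
re-engagement is gradual, so earlier samples mix saccade tail into the
ratio. (An earlier variant that instead started at the first
counter-rotation sample was abandoned: selecting a sample on the sign of
its noisy eye velocity biased the ratio upward by about 3%.)

Relative timing uses mean eye and head velocities over the 100 ms before
and after the saccade onset; a shift is head-led when the pre-onset head
speed exceeds 5 deg/s in the same direction as the post-onset head
movement. This velocity-based comparison is deliberate: some participants
never fully stabilize the head, so a head-movement-onset time does not
exist for them. The wider -250 ms to +750 ms span around the onset is the
per-event analysis epoch for plots and peak extraction, not the averaging
window; the source material is ambiguous between the two, so both are
computed and the 100-ms pair drives classification.

The coordination summary reports per-condition means and standard errors
of saccade amplitude, gaze amplitude, peak saccade velocity, saccade
duration and peak head velocity; the head-velocity slope (regression
through the origin of per-event peak head velocity on gaze amplitude); the
head-led fraction; and a sublinearity flag (the saccade/gaze amplitude
ratio decreases across conditions). Because "gaze angle" on a
main-sequence abscissa can mean the nominal target separation or the
measured amplitude, the table carries both the condition label and the
measured mean.

## The simulator

The generator is the package's ground-truth oracle and emulates the
measurement protocol: a zero fixation (head-yaw reference), a 23-fixation
calibration sweep over the 12 wall targets (right to left and back),
head-shake synchronization episodes before, between and after six
target-separation conditions (17.6, 38.3, 63.3, 91.2, 118.9, 143.6
degrees), and 45 alternating self-paced shifts per condition.

**Kinematics.** Both effectors move with raised-cosine (bell) velocity
profiles. The saccade follows the main sequence
$V_{peak} = V_{max}(1 - e^{-A/A_{63}})$ with defaults
$V_{max} = 500$ deg/s, $A_{63} = 14$ deg (an 80-deg saccade then lasts
about 0.3 s); bell duration is $2A/V_{peak}$. The head bell's peak
velocity is pinned at `head_velocity_slope * gaze_amplitude` (default
2.31 1/s) and starts `head_lead` seconds before the saccade (default
80 ms). Outside the saccade the eye counter-rotates at the VOR gain
(default 1), so gaze is flat there *by construction*.

**Amplitude sharing.** The saccade carries `A (1 - 0.1 A / 35)` of a gaze
amplitude up to 35 degrees and a 0.38 marginal share beyond, capped at 80
degrees -- a two-piece rule whose saccade/gaze ratio decreases strictly
with amplitude. The share is raised to the minimum kinematically
achievable value whenever the head bell cannot close the shift within the
saccade window (this binds for the 91.2- and 118.9-deg conditions).
A pure-unity share below the kink was rejected because it would leave the
smallest conditions with no head movement after the saccade onset,
which contradicts the head-led character of predictable-target shifts.

**Closure.** The only free kinematic parameter per shift is the head-bell
duration, solved by root finding so that
$A_{gaze} = A_{sacc} + g I + (1-g) H_{total}$, where $I$ is the head
displacement inside the saccade not VOR-compensated. The smaller of the
two candidate durations is used; it keeps post-saccadic head movement
small, which in turn keeps eye-in-head excursions inside the +-40-degree
oculomotor range even for the 143.6-degree condition.

**VOR switching.** Suppression is not instantaneous: the VOR weight falls
from 1 to 0 over a 15-ms cosine ramp just inside the saccade onset and
returns symmetrically before the offset. Besides being closer to the
physiology, this keeps gaze velocity continuous, so the 10%-of-peak
onset/offset landmarks are well conditioned; with an instantaneous switch
the landmark sits on a velocity step and sampled-data detection is
systematically several milliseconds late. Outside the saccade interval
dE = -g dH holds exactly.

**Ground truth bookkeeping.** The truth table stores, per shift, the
saccade bell boundaries, the 10%-of-peak gaze-velocity landmarks computed
from the analytic velocity on a 0.5-ms grid, full-shift amplitudes, *and*
amplitudes between the landmarks. The detector's amplitudes are
displacements between its own 10% landmarks, which exclude the
sub-threshold velocity tails (about half a degree on the largest shifts),
so recovery tests compare landmark-to-landmark -- the like-for-like
comparison.

**Rendering.** Head yaw (plus a fixed marker mounting tilt of 2/1 degrees
pitch/roll and an arbitrary mounting yaw) is turned into marker poses and
projected through the ceiling-camera pinhole model to corner pixels at
250 Hz; eye azimuth plus the scene-camera mounting bias (-c, default
c = 1.2 deg) is inverted through the tangent map to pixels. Eye
timestamps follow the bimodal 4/8-ms mixture, laid out by cumulative
rounding with local shuffling so the realized effective rate matches the
requested 200.54 Hz to within ~0.1 Hz (an iid Bernoulli mixture wobbles
several times more). A true clock offset (default 0.2 s) shifts the eye
stream. Gaussian angle noise defaults to 0.05 deg (eye) and 0.02 deg
(head). Between-block transitions are slow gaze movements with peak
velocity 35 deg/s -- below the detection threshold -- so the detected
event inventory is exactly the per-condition shifts.

**What the simulator does not emulate.** Blinks and tracker dropouts (the
protocol instructs participants not to blink during shifts; an injector is
out of scope), lens distortion, marker-detection failures, head
translation, torsion and vertical components, trial-to-trial amplitude
variability (shifts within a condition are kinematically identical, so
per-condition standard errors reflect measurement noise only), and
between-participant strategy differences. A green recovery test therefore
establishes that the pipeline inverts this stated world faithfully -- not
that it handles artifacts the generator never produces.

## Numerical choices

* Homography from 4 points via an 8 x 8 linear solve (exact in the
  noise-free case to ~1e-12); nearest-rotation projection by SVD with a
  determinant guard.
* Rodrigues conversions invert each other for rotation angles in
  (0, pi); near pi the axis is recovered from the symmetric part.
* Euler extraction errors out within 1 degree of gimbal lock
  (|pitch| = 90 deg); head-yaw extraction refuses |pitch| > 85 deg.
* Ties and degeneracies: degenerate (collinear) corner sets error out;
  an all-invalid calibration window yields NA and is excluded from the
  fit; a head already stationary at saccade offset yields an empty VOR
  phase with NA gain.
* The one-dimensional two-means clustering initializes at the extremes
  and declares unimodality when the centers are closer than four pooled
  within-cluster standard deviations.

## Limitations

Single-axis (yaw) analysis only; c is a global constant, so slippage of
the eye tracker over a session is not corrected; the pose estimator's
accuracy degrades at marker tilts beyond ~10 degrees from fronto-parallel
(no iterative refinement); event detection assumes a functioning VOR
(gaze-stable inter-saccadic intervals) and will over-segment data where
gaze drifts at tens of degrees per second for other reasons.
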