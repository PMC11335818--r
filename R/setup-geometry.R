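#' Analytic setup-geometry quantities
#'
#' Small closed-form helpers describing the measurement geometry of a
#' room-scale gaze-tracking setup; useful for judging how design choices
#' (target distance, target size, head translation) limit the achievable
#' angular accuracy.
#'
#' * `translation_gaze_error()` -- absolute gaze-angle error caused by a
#'   lateral head translation while fixating a target at a given distance:
#'   `atan(translation / distance)`. A 5-cm translation at the closest
#'   (~2.45 m) target costs about 1.2 degrees.
#' * `angular_size()` -- visual angle subtended by a target of a given
#'   diameter: `2 atan(diameter / 2 / distance)` (0.13 degrees for the
#'   0.8-cm targets at 3.43 m, 0.18 degrees at 2.5 m).
#' * `height_offset_angle()` -- vertical gaze angle of a target mounted a
#'   given height away from eye level (1.6 degrees for a 7-cm offset at
#'   2.45 m).
#' * `window_duration()` -- duration covered by an n-sample precision window
#'   (n x dt bookkeeping: 41 samples at 200 Hz = 205 ms).
#'
#' @param translation Lateral head translation, meters.
#' @param distance Target distance, meters.
#' @return Degrees (seconds for `window_duration`).
#' @export
translation_gaze_error <- function(translation, distance) {
  atan(translation / distance) * 180 / pi
}

#' @rdname translation_gaze_error
#' @param diameter Target diameter, meters.
#' @export
angular_size <- function(diameter, distance) {
  2 * atan(diameter / 2 / distance) * 180 / pi
}

#' @rdname translation_gaze_error
#' @param height Vertical offset from eye level, meters.
#' @export
height_offset_angle <- function(height, distance) {
  atan(height / distance) * 180 / pi
}

#' @rdname translation_gaze_error
#' @param n_samples Samples per window.
#' @param rate Sampling rate, Hz.
#' @export
window_duration <- function(n_samples, rate) {
  n_samples / rate
}
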