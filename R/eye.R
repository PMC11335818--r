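#' Convert scene-camera gaze pixels to eye-in-head angles
#'
#' The wearable eye tracker reports the gaze point in scene-camera pixel
#' coordinates; under the ideal pinhole model a pixel maps to a visual
#' direction by the tangent relation
#' `azimuth = atan((px - x) / f)`, `elevation = atan((py - y) / f)`,
#' with `(px, py)` the principal point and `f = (width/2) / tan(fov_h/2)`.
#' Azimuth is positive toward the participant's left and elevation positive
#' up, consistent with the head-yaw sign convention so that G = E + H + c
#' holds sign-correctly. The mapping is a true tangent, not a small-angle
#' linearization: an edge pixel of the 82-degree scene camera subtends
#' exactly 41 degrees.
#'
#' @param samples Data frame with columns `timestamp`, `x_px`, `y_px`,
#'   `valid` (a single sample may be given as a 1-row data frame).
#' @param camera A [camera_model()] for the scene camera, e.g.
#'   [scene_camera()].
#' @return Data frame `timestamp, azimuth_deg, elevation_deg, valid`;
#'   invalid input samples propagate as invalid with NA angles.
#' @examples
#' cam <- scene_camera()
#' s <- data.frame(timestamp = 0, x_px = 0, y_px = 540, valid = TRUE)
#' pixels_to_angles(s, cam)$azimuth_deg  # 41 = half the field of view
#' @export
pixels_to_angles <- function(samples, camera) {
  if (missing(camera) || !inherits(camera, "camera_model")) {
    stop("a scene `camera_model` is required to convert pixels to angles")
  }
  stopifnot(all(c("timestamp", "x_px", "y_px") %in% names(samples)))
  valid <- if ("valid" %in% names(samples)) as.logical(samples$valid) else
    rep(TRUE, nrow(samples))
  valid <- valid & is.finite(samples$x_px) & is.finite(samples$y_px)
  f <- camera$focal_length
  pp <- camera$principal_point
  az <- atan((pp[1] - samples$x_px) / f) * 180 / pi
  el <- atan((pp[2] - samples$y_px) / f) * 180 / pi
  az[!valid] <- NA_real_
  el[!valid] <- NA_real_
  data.frame(timestamp = samples$timestamp, azimuth_deg = az,
             elevation_deg = el, valid = valid)
}

#' Inverse of [pixels_to_angles()]
#'
#' Maps eye-in-head angles back to scene-camera pixels; used by the
#' simulator to render eye-tracker samples and exactly inverts the tangent
#' mapping.
#'
#' @param azimuth_deg,elevation_deg Angles in degrees (positive left / up).
#' @param camera A [camera_model()].
#' @return Data frame `x_px, y_px`.
#' @export
angles_to_pixels <- function(azimuth_deg, elevation_deg, camera) {
  stopifnot(inherits(camera, "camera_model"))
  f <- camera$focal_length
  pp <- camera$principal_point
  data.frame(x_px = pp[1] - f * tan(azimuth_deg * pi / 180),
             y_px = pp[2] - f * tan(elevation_deg * pi / 180))
}
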