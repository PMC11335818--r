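#' Fuse eye-in-head and head signals into world-fixed gaze
#'
#' Given eye-in-head (E) and head (H) angle streams on the same uniform time
#' grid, computes the gaze angle G = E + H + c at every sample, together with
#' velocity channels by central difference. A sample is invalid whenever
#' either input is invalid.
#'
#' @param E,H Uniform [sampled_signal()]s on identical grids (degrees).
#' @param c_deg Additive calibration constant c in degrees (default 0; see
#'   [calibrate_constant()]).
#' @return A `gaze_record`: a data frame with columns `time`, `E_deg`,
#'   `H_deg`, `G_deg`, `dE_dps`, `dH_dps`, `dG_dps`, `valid` and attributes
#'   `rate_hz` and `c_deg`.
#' @export
fuse <- function(E, H, c_deg = 0) {
  stopifnot(inherits(E, "sampled_signal"), inherits(H, "sampled_signal"))
  if (length(E$timestamps) != length(H$timestamps) ||
      max(abs(E$timestamps - H$timestamps)) > 1e-9) {
    stop("E and H must share the same uniform time grid; resample both ",
         "with a common `range` first")
  }
  dts <- diff(E$timestamps)
  if (length(dts) < 1 || diff(range(dts)) > 1e-9) {
    stop("E and H must be uniformly sampled")
  }
  dt <- dts[1]
  valid <- E$valid & H$valid
  G <- E$values + H$values + c_deg
  rec <- data.frame(
    time = E$timestamps,
    E_deg = E$values, H_deg = H$values, G_deg = G,
    dE_dps = estimate_velocity(E$values, dt),
    dH_dps = estimate_velocity(H$values, dt),
    dG_dps = estimate_velocity(G, dt),
    valid = valid)
  attr(rec, "rate_hz") <- 1 / dt
  attr(rec, "c_deg") <- c_deg
  class(rec) <- c("gaze_record", "data.frame")
  rec
}

#' @export
print.gaze_record <- function(x, ...) {
  cat(sprintf("<gaze_record> %d samples at %.1f Hz (%.1f s), c = %.3f deg\n",
              nrow(x), attr(x, "rate_hz"),
              nrow(x) / attr(x, "rate_hz"), attr(x, "c_deg")))
  invisible(x)
}

#' Calibrate the additive gaze constant c
#'
#' The raw sum E + H differs from the world-fixed gaze angle by a constant
#' (scene-camera mounting offset plus the arbitrary marker zero); c is fit by
#' least squares over the calibration fixations so that the corrected gaze
#' matches the known target azimuths, which sets the gaze zero in the corner
#' of the room. With one free constant the least-squares minimizer of
#' sum((median(G_raw in window) + c - target)^2) is the mean of
#' (target - median window gaze). Each fixation is summarized by the median
#' of the central 50% of its window, making the fit robust to microsaccades
#' and window-edge transients.
#'
#' @param G_raw A [sampled_signal()] holding uncalibrated gaze E + H
#'   (degrees).
#' @param fixation_windows Data frame with columns `t0`, `t1` (seconds), one
#'   row per calibration fixation.
#' @param target_azimuths Numeric vector of world-fixed target azimuths in
#'   degrees, one per window.
#' @param central_fraction Fraction of each window, centred, used for the
#'   median (default 0.5).
#' @return A `calibration_result` list: `c_deg`, `per_target_error_deg`,
#'   `mean_absolute_error_deg`, `n_windows`.
#' @export
calibrate_constant <- function(G_raw, fixation_windows, target_azimuths,
                               central_fraction = 0.5) {
  stopifnot(inherits(G_raw, "sampled_signal"),
            nrow(fixation_windows) == length(target_azimuths),
            nrow(fixation_windows) >= 1)
  med <- fixation_medians(G_raw, fixation_windows, central_fraction)
  ok <- is.finite(med)
  if (!any(ok)) stop("no valid samples in any fixation window")
  if (length(unique(target_azimuths[ok])) < 2) {
    warning("fewer than 2 distinct targets: c is estimable but unvalidated")
  }
  c_deg <- mean(target_azimuths[ok] - med[ok])
  resid <- med + c_deg - target_azimuths
  structure(
    list(c_deg = c_deg,
         per_target_error_deg = resid,
         mean_absolute_error_deg = mean(abs(resid[ok])),
         n_windows = sum(ok)),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> c = %.3f deg, MAE = %.3f deg over %d windows\n",
              x$c_deg, x$mean_absolute_error_deg, x$n_windows))
  invisible(x)
}

# median signal value over the central fraction of each window
fixation_medians <- function(signal, windows, central_fraction = 0.5) {
  vapply(seq_len(nrow(windows)), function(i) {
    t0 <- windows$t0[i]; t1 <- windows$t1[i]
    pad <- (t1 - t0) * (1 - central_fraction) / 2
    sel <- signal$valid & signal$timestamps >= t0 + pad &
      signal$timestamps <= t1 - pad
    if (!any(sel)) return(NA_real_)
    stats::median(signal$values[sel])
  }, numeric(1))
}

#' Run the full processing pipeline on one recording
#'
#' Chains every stage: head pose estimation from marker corners, eye pixel to
#' angle conversion, clock synchronization on the head-oscillation episodes,
#' resampling both streams to a common uniform grid, fusion into gaze, and
#' calibration of the constant c against the target table.
#'
#' @param markers Marker observation table (see [read_marker_csv()]).
#' @param eye_samples Eye sample table (see [read_eye_csv()]).
#' @param targets Calibration table with columns `t0`, `t1`, `azimuth_deg`
#'   (fixation windows in head-clock seconds and target azimuths).
#' @param ceiling_cam,scene_cam [camera_model()]s for the two cameras.
#' @param marker A [marker_model()].
#' @param rate_hz Common grid rate (default 200).
#' @param sync_search_s Synchronization search window, seconds.
#' @param sync_segments Optional oscillation-episode table for
#'   [synchronize()].
#' @param reference_window Length-2 numeric: time window of the zero fixation
#'   used for the head-yaw reference; defaults to the first second of the
#'   recording.
#' @return List with elements `record` (calibrated `gaze_record`),
#'   `calibration`, `sync_offset_s`, `pose_series`, `eye_angles`.
#' @export
gaze_pipeline <- function(markers, eye_samples, targets, ceiling_cam,
                          scene_cam, marker, rate_hz = 200,
                          sync_search_s = 1, sync_segments = NULL,
                          reference_window = NULL) {
  poses <- estimate_head_pose_series(markers, marker, ceiling_cam)
  if (is.null(reference_window)) {
    reference_window <- poses$timestamp[1] + c(0, 1)
  }
  ref <- estimate_reference_yaw(poses, reference_window)
  poses$yaw_deg <- wrap_angle(poses$yaw_deg - ref)
  H_raw <- sampled_signal(poses$timestamp, poses$yaw_deg, poses$valid)

  ang <- pixels_to_angles(eye_samples, scene_cam)
  E_raw <- sampled_signal(ang$timestamp, ang$azimuth_deg, ang$valid)

  offset <- synchronize(E_raw, H_raw, search_window = sync_search_s,
                        rate = rate_hz, segments = sync_segments)
  E_sync <- sampled_signal(E_raw$timestamps - as.numeric(offset),
                           E_raw$values, E_raw$valid)

  t0 <- max(min(E_sync$timestamps[E_sync$valid]),
            min(H_raw$timestamps[H_raw$valid]))
  t1 <- min(max(E_sync$timestamps[E_sync$valid]),
            max(H_raw$timestamps[H_raw$valid]))
  Eu <- resample_to_rate(E_sync, rate_hz, range = c(t0, t1))
  Hu <- resample_to_rate(H_raw, rate_hz, range = c(t0, t1))

  raw <- fuse(Eu, Hu, c_deg = 0)
  G_raw <- sampled_signal(raw$time, raw$G_deg, raw$valid)
  cal <- calibrate_constant(G_raw, targets[, c("t0", "t1")],
                            targets$azimuth_deg)
  rec <- fuse(Eu, Hu, c_deg = cal$c_deg)

  list(record = rec, calibration = cal, sync_offset_s = as.numeric(offset),
       sync_peak_correlation = attr(offset, "peak_correlation"),
       pose_series = poses, eye_angles = ang)
}
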