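# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths where they serve as a cross-check.

# brute-force projection oracle: explicit per-corner rotate, translate,
# perspective divide (no shared code with project_marker)
oracle_project <- function(R, tvec, marker_side, f, pp) {
  h <- marker_side / 2
  corners <- list(c(-h, -h, 0), c(h, -h, 0), c(h, h, 0), c(-h, h, 0))
  t(vapply(corners, function(p) {
    q <- as.numeric(R %*% p + tvec)
    c(f * q[1] / q[3] + pp[1], f * q[2] / q[3] + pp[2])
  }, numeric(2)))
}

# independent pixel-to-azimuth oracle: build the 3-D back-projected ray and
# measure its angle to the optical axis in the horizontal plane
oracle_pixel_azimuth <- function(x_px, camera) {
  ray <- c(camera$principal_point[1] - x_px, 0, camera$focal_length)
  sign(ray[1]) * acos(ray[3] / sqrt(sum(ray^2))) * 180 / pi
}

# random proper rotation with bounded pitch/roll
random_pose <- function(yaw_max = 60, tilt_max = 20) {
  euler_to_matrix(runif(1, -yaw_max, yaw_max),
                  runif(1, -tilt_max, tilt_max),
                  runif(1, -tilt_max, tilt_max))
}

# uniform sampled_signal shortcut
uniform_signal <- function(values, rate = 200, t0 = 0) {
  sampled_signal(t0 + (seq_along(values) - 1) / rate, values)
}

# build a gaze_record directly from truth traces sampled at `rate`
record_from_truth <- function(segments, rate = 200, t0 = NULL, t1 = NULL) {
  starts <- vapply(segments, `[[`, numeric(1), "t0")
  durs <- vapply(segments, `[[`, numeric(1), "dur")
  if (is.null(t0)) t0 <- min(starts)
  if (is.null(t1)) t1 <- max(starts + durs)
  tt <- seq(t0, t1, by = 1 / rate)
  tr <- headgaze:::segments_eval(segments, tt)
  fuse(sampled_signal(tt, tr$E), sampled_signal(tt, tr$H), 0)
}

# small simulated session shared by several test files (cached per run)
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(shifts_per_condition = 3,
                        target_separations = c(38.3, 118.9),
                        fixation_pause = 2, calib_fix_duration = 3,
                        seed = 42L)
      cache <<- simulate_session(cfg)
    }
    cache
  }
})
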