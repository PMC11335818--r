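test_that("accuracy averages absolute per-window errors of the median gaze", {
  rec <- record_from_truth(list(list(type = "fixation", t0 = 0, dur = 10,
                                     e0 = 0, h0 = 0)))
  win <- data.frame(t0 = c(1, 6), t1 = c(4, 9))
  # gaze is identically 0; targets at -10 and 10 with medians shifted +-0.5
  rec$G_deg <- ifelse(rec$time < 5, -10.5, 10.5)
  expect_equal(as.numeric(accuracy(rec, win, c(-10, 10))), 0.5)
  rec$G_deg <- ifelse(rec$time < 5, -10, 10)
  expect_equal(as.numeric(accuracy(rec, win, c(-10, 10))), 0)
  expect_error(accuracy(rec, data.frame(t0 = 20, t1 = 21), 0), "no valid")
})

test_that("accuracy recovers injected per-target biases", {
  set.seed(12)
  n_t <- 8
  bias <- rnorm(n_t, 0, 1)
  tt <- seq(0, n_t * 2, by = 0.005)
  G <- numeric(length(tt))
  win <- data.frame(t0 = (seq_len(n_t) - 1) * 2 + 0.2,
                    t1 = (seq_len(n_t) - 1) * 2 + 1.8)
  targets <- seq(-35, 35, length.out = n_t)
  for (i in seq_len(n_t)) {
    sel <- tt >= win$t0[i] - 0.2 & tt <= win$t1[i] + 0.2
    G[sel] <- targets[i] + bias[i]
  }
  G <- G + rnorm(length(G), 0, 0.05)
  rec <- fuse(uniform_signal(G), uniform_signal(numeric(length(G))), 0)
  rec$time <- tt[seq_len(nrow(rec))]
  expect_equal(as.numeric(accuracy(rec, win, targets)), mean(abs(bias)),
               tolerance = 0.02)
})

test_that("RMS-S2S handles the closed-form cases", {
  expect_equal(rms_s2s_precision(uniform_signal(rep(2.5, 300))), 0)
  a <- 0.3
  alt <- rep(c(a, -a), 150)
  expect_equal(rms_s2s_precision(uniform_signal(alt)), 2 * a)
  expect_error(rms_s2s_precision(uniform_signal(rnorm(20)), 41), "shorter")
})

test_that("RMS-S2S obeys the sigma sqrt(2) law, shift/scale behaviour", {
  set.seed(13)
  x <- rnorm(4000, 0, 0.05)
  r <- rms_s2s_precision(uniform_signal(x))
  expect_equal(r, 0.05 * sqrt(2), tolerance = 0.05)
  expect_equal(rms_s2s_precision(uniform_signal(x + 100)), r)
  expect_equal(rms_s2s_precision(uniform_signal(3 * x)), 3 * r,
               tolerance = 1e-12)
})

test_that("median-over-windows is robust to saccade contamination", {
  set.seed(14)
  x <- rnorm(6000, 0, 0.05)
  # inject 10 saccade-like 20-deg steps: < 50% of windows contaminated
  for (k in seq_len(10)) x[(k * 550):6000] <- x[(k * 550):6000] + 20
  sig <- uniform_signal(x)
  med <- rms_s2s_precision(sig)
  overall <- sqrt(mean(diff(x)^2))
  expect_lt(med, overall)
  expect_equal(med, 0.05 * sqrt(2), tolerance = 0.1)
})

test_that("windows containing invalid samples are skipped", {
  set.seed(15)
  x <- rnorm(2000, 0, 0.05)
  valid <- rep(TRUE, 2000)
  x[800:820] <- 50   # a blink-like excursion, flagged invalid
  valid[800:820] <- FALSE
  r <- rms_s2s_precision(sampled_signal((0:1999) / 200, x, valid))
  expect_equal(r, 0.05 * sqrt(2), tolerance = 0.1)
})

test_that("effective frequency is valid count over span", {
  tt <- seq(0, 2, length.out = 400)   # spans exactly 2 s
  expect_equal(effective_frequency(tt), 200)
  tt2 <- seq(0, 2, length.out = 500)
  valid <- c(rep(TRUE, 401), rep(FALSE, 99))
  expect_equal(effective_frequency(tt2, valid), 200.5)
  expect_error(effective_frequency(c(1, 1)), "zero-duration")
  # gap-free uniform stream: nominal rate up to edge effects < 0.5%
  tt3 <- (0:999) / 250
  expect_lt(abs(effective_frequency(tt3) - 250) / 250, 0.005)
})

test_that("interval distribution separates the bimodal mixture", {
  # strict 5-ms spacing: one mode, zero sd
  d <- interval_distribution((0:199) * 0.005)
  expect_equal(nrow(d), 1)
  expect_equal(d$mode_ms, 5, tolerance = 1e-9)
  expect_equal(d$sd_ms, 0, tolerance = 1e-9)

  # interleaved exact 4/8 ms: two exact modes with zero sd
  tt <- cumsum(rep(c(0.004, 0.008), 100))
  d2 <- interval_distribution(tt)
  expect_equal(d2$mode_ms, c(4, 8), tolerance = 1e-9)
  expect_equal(d2$sd_ms, c(0, 0), tolerance = 1e-9)

  # 70/30 gaussian mixture around 4 and 8 ms, sd 0.08 ms
  set.seed(16)
  ints <- ifelse(runif(5000) < 0.7, rnorm(5000, 0.004, 8e-5),
                 rnorm(5000, 0.008, 8e-5))
  d3 <- interval_distribution(cumsum(ints))
  expect_equal(d3$mode_ms, c(4, 8), tolerance = 0.05)
  expect_equal(d3$sd_ms, c(0.08, 0.08), tolerance = 0.015)
  expect_equal(d3$weight, c(0.7, 0.3), tolerance = 0.03)
})

test_that("quality_report bundles the metrics for a simulated session", {
  ses <- small_session()
  res <- gaze_pipeline(ses$markers, ses$eye, ses$targets,
                       ses$truth$ceiling_camera, ses$truth$scene_camera,
                       ses$truth$marker,
                       sync_segments = ses$truth$oscillation_windows,
                       reference_window = ses$truth$reference_window)
  ang <- res$eye_angles
  E_raw <- sampled_signal(ang$timestamp, ang$azimuth_deg, ang$valid)
  poses <- res$pose_series
  H_raw <- sampled_signal(poses$timestamp, poses$yaw_deg, poses$valid)
  q <- quality_report(res$record, E_raw, H_raw,
                      ses$targets[, c("t0", "t1")], ses$targets$azimuth_deg)
  cfg <- ses$truth$config
  expect_lt(q$mean_absolute_accuracy_deg, 0.1)
  # sigma sqrt(2) recovery on the raw streams
  expect_equal(unname(q$precision_rms_s2s_deg["E"]),
               cfg$eye_noise_sd * sqrt(2), tolerance = 0.1)
  expect_equal(unname(q$precision_rms_s2s_deg["H"]),
               cfg$head_noise_sd * sqrt(2), tolerance = 0.1)
  expect_lt(abs(q$effective_frequency_hz - cfg$eye_effective_rate), 0.1)
  expect_lt(max(abs(q$interval_modes$mode_ms - c(4, 8))), 0.05)
  # loose triangle-type bound
  expect_lt(q$precision_rms_s2s_deg["G"],
            q$precision_rms_s2s_deg["E"] + q$precision_rms_s2s_deg["H"] +
              0.01)
})
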