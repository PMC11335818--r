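test_that("resampling is exact on uniform and linear input and idempotent", {
  x <- sin(seq(0, 4, by = 1 / 200))
  s <- uniform_signal(x)
  r <- resample_to_rate(s, 200)
  expect_equal(r$values, x, tolerance = 1e-12)
  expect_equal(diff(r$timestamps), rep(1 / 200, length(x) - 1),
               tolerance = 1e-12)
  r2 <- resample_to_rate(r, 200)
  expect_equal(r2$values, r$values, tolerance = 1e-12)

  set.seed(2)
  tt <- cumsum(runif(400, 0.001, 0.02))
  ramp <- sampled_signal(tt, 10 * tt)
  rr <- resample_to_rate(ramp, 200)
  expect_equal(rr$values, 10 * rr$timestamps, tolerance = 1e-9)

  const <- resample_to_rate(sampled_signal(tt, rep(3.2, 400)), 200)
  expect_true(all(const$values == 3.2))
})

test_that("resampling a bimodal-interval sinusoid stays within 0.05 deg", {
  set.seed(3)
  ints <- ifelse(runif(1200) < 0.75, rnorm(1200, 0.004, 8e-5),
                 rnorm(1200, 0.008, 8e-5))
  tt <- cumsum(ints)
  s <- sampled_signal(tt, 10 * sin(2 * pi * 2 * tt))
  r <- resample_to_rate(s, 200)
  expect_lt(max(abs(r$values - 10 * sin(2 * pi * 2 * r$timestamps))), 0.05)
})

test_that("resampling marks grid points far from valid samples invalid", {
  tt <- c(seq(0, 1, by = 0.005), seq(1.5, 2.5, by = 0.005))
  s <- sampled_signal(tt, rep(1, length(tt)))
  r <- resample_to_rate(s, 200)
  in_gap <- r$timestamps > 1.0501 & r$timestamps < 1.4499
  expect_true(all(!r$valid[in_gap]))
  expect_true(all(r$valid[!in_gap]))
  expect_error(resample_to_rate(sampled_signal(0.1, 1), 200), "2 valid")
})

test_that("synchronize recovers clock offsets on oscillation episodes", {
  osc <- simulate_oscillation(6, 1, 10)
  tt <- seq(0, 6, by = 0.005)
  tr <- headgaze:::segments_eval(osc$segments, tt)
  H <- sampled_signal(tt, tr$H)
  E0 <- sampled_signal(tt, tr$E)
  off0 <- synchronize(E0, H, search_window = 0.5,
                      segments = data.frame(t0 = 0, t1 = 6))
  expect_lt(abs(as.numeric(off0)), 5e-4)

  # eye clock ahead by 37 ms: eye sample at t really happened at t - 0.037
  E37 <- sampled_signal(tt + 0.037, tr$E)
  off37 <- synchronize(E37, H, search_window = 0.5,
                       segments = data.frame(t0 = 0, t1 = 6))
  expect_lt(abs(as.numeric(off37) - 0.037), 2.5e-3)

  # shift-equivariance: shifting the eye stream moves the offset equally
  E2 <- sampled_signal(E37$timestamps + 0.1, E37$values)
  off2 <- synchronize(E2, H, search_window = 0.5,
                      segments = data.frame(t0 = 0, t1 = 6))
  expect_lt(abs((as.numeric(off2) - as.numeric(off37)) - 0.1), 1e-3)
})

test_that("synchronize fails loudly without an oscillation signature", {
  set.seed(4)
  tt <- seq(0, 6, by = 0.005)
  E <- sampled_signal(tt, rnorm(length(tt), 0, 0.05))
  H <- sampled_signal(tt, rnorm(length(tt), 0, 0.02))
  expect_error(synchronize(E, H, segments = data.frame(t0 = 0, t1 = 6)),
               "no oscillation signature")
})

test_that("fuse adds channels, requires a shared grid, and is exact", {
  E <- uniform_signal(rep(30, 400))
  H <- uniform_signal(rep(40, 400))
  rec <- fuse(E, H, 0)
  expect_true(all(rec$G_deg == 70))
  expect_error(fuse(E, uniform_signal(rep(1, 400), t0 = 0.001)), "grid")
  expect_error(fuse(E, uniform_signal(rep(1, 300))), "grid")

  # gain-1 VOR: E = -H cancels exactly
  h <- 15 * sin(seq(0, 6 * pi, length.out = 500))
  rec2 <- fuse(uniform_signal(-h), uniform_signal(h), 0)
  expect_lt(max(abs(rec2$G_deg)), 1e-12)

  # additivity identity at arbitrary c
  set.seed(9)
  e <- cumsum(rnorm(300)); hh <- cumsum(rnorm(300))
  rec3 <- fuse(uniform_signal(e), uniform_signal(hh), 12.3)
  expect_lt(max(abs(rec3$G_deg - rec3$E_deg - rec3$H_deg - 12.3)), 1e-9)

  # validity: invalid in either input invalidates the sample
  Ei <- sampled_signal(E$timestamps, E$values,
                       c(FALSE, rep(TRUE, 399)))
  expect_false(fuse(Ei, H, 0)$valid[1])
})

test_that("calibrate_constant recovers offsets and reports residuals", {
  tt <- seq(0, 30, by = 0.005)
  targets <- c(-20, -10, 0, 10, 20)
  win <- data.frame(t0 = seq(1, by = 6, length.out = 5))
  win$t1 <- win$t0 + 4
  G <- numeric(length(tt))
  for (i in seq_len(5)) {
    G[tt >= win$t0[i] - 1 & tt <= win$t1[i] + 1] <- targets[i] + 5
  }
  cal <- calibrate_constant(sampled_signal(tt, G), win, targets)
  expect_equal(cal$c_deg, -5, tolerance = 1e-12)
  expect_equal(cal$mean_absolute_error_deg, 0, tolerance = 1e-12)

  # symmetric zero-mean +-1 deg systematic residuals leave c unchanged and
  # appear verbatim in the per-target errors
  resid <- c(-1, 1, 1, -1, 0)
  G2 <- numeric(length(tt))
  for (i in seq_len(5)) {
    sel <- tt >= win$t0[i] - 1 & tt <= win$t1[i] + 1
    G2[sel] <- targets[i] + 5 + resid[i]
  }
  cal2 <- calibrate_constant(sampled_signal(tt, G2), win, targets)
  expect_equal(cal2$c_deg, -5, tolerance = 1e-12)
  expect_equal(cal2$per_target_error_deg, resid, tolerance = 1e-12)

  expect_warning(
    calibrate_constant(sampled_signal(tt, G), win[1, ], targets[1]),
    "fewer than 2")
})

test_that("calibration recovers c = 12.3 from a simulated sweep", {
  # small separations keep eye-in-head + the 12.3-deg mounting bias
  # inside the scene camera image
  cfg <- sim_config(target_separations = c(17.6, 63.3),
                    shifts_per_condition = 1,
                    calibration_constant_true = 12.3,
                    eye_noise_sd = 0.05, seed = 8L)
  ses <- simulate_session(cfg)
  res <- gaze_pipeline(ses$markers, ses$eye, ses$targets,
                       ses$truth$ceiling_camera, ses$truth$scene_camera,
                       ses$truth$marker,
                       sync_segments = ses$truth$oscillation_windows,
                       reference_window = ses$truth$reference_window)
  expect_lt(abs(res$calibration$c_deg - 12.3), 0.05)
})
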