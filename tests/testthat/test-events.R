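# clean (noise-free) records sampled straight from simulator truth
shift_record <- function(amplitude, config = sim_config(), rate = 200, ...) {
  s <- simulate_gaze_shift(amplitude, config, ...)
  list(rec = record_from_truth(s$segments, rate), truth = s)
}

test_that("a single clean 90-deg shift yields one accurately timed event", {
  sr <- shift_record(90)
  ev <- detect_gaze_saccades(sr$rec)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$saccade_onset_s - sr$truth$event$t_onset), 0.005)
  expect_lt(abs(ev$saccade_offset_s - sr$truth$event$t_offset), 0.005)
  expect_equal(ev$gaze_amplitude_deg, sr$truth$event$gaze_amplitude_land,
               tolerance = 0.5 / 90)
  expect_equal(ev$saccade_amplitude_deg,
               sr$truth$event$saccade_amplitude_land,
               tolerance = 0.5 / 40)
  expect_equal(ev$peak_head_velocity_dps, sr$truth$event$peak_head_velocity,
               tolerance = 0.02)
  # decomposition consistency: gaze = eye + head displacement over saccade
  expect_lt(abs(ev$gaze_displacement_deg -
                  (ev$saccade_displacement_deg +
                     ev$head_during_saccade_deg)), 1)
})

test_that("gain-1 VOR head oscillation under fixation yields no events", {
  osc <- simulate_oscillation(6, 1, 12)
  rec <- record_from_truth(osc$segments)
  ev <- detect_gaze_saccades(rec)
  expect_equal(nrow(ev), 0)
  # gaze stays flat while the head moves fast
  expect_lt(max(abs(rec$dG_dps[rec$valid]), na.rm = TRUE), 5)
  expect_gt(max(abs(rec$dH_dps), na.rm = TRUE), 60)
})

test_that("vor_phase recovers the configured gain", {
  for (g in c(1.0, 0.9)) {
    sr <- shift_record(120, sim_config(vor_gain = g))
    ev <- detect_gaze_saccades(sr$rec)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$vor_gain, g, tolerance = 0.02)
    vp <- vor_phase(sr$rec, ev[1, ])
    expect_equal(vp$gain, g, tolerance = 0.02)
    expect_gt(vp$t_end, vp$t_start)
  }
})

test_that("an empty VOR phase is reported when the head is already still", {
  # small shift: the brief head nod ends inside the saccade interval
  sr <- shift_record(17.6)
  ev <- detect_gaze_saccades(sr$rec)
  expect_equal(nrow(ev), 1)
  vp <- vor_phase(sr$rec, ev[1, ])
  expect_true(is.na(vp$t_start) || vp$t_end - vp$t_start < 0.02)
})

test_that("pre/post velocities separate head-lead from eye-lead shifts", {
  lead <- shift_record(90, sim_config(head_lead = 0.08))
  ev <- detect_gaze_saccades(lead$rec)
  pp <- pre_post_velocities(lead$rec, ev[1, ])
  # VOR before the saccade: eye mirrors head (-45 deg line)
  expect_equal(unname(pp["pre_eye"]), -unname(pp["pre_head"]),
               tolerance = 0.05 * abs(pp[["pre_head"]]) + 0.5)
  expect_gt(abs(pp[["pre_head"]]), 5)
  # rising head bell: post-onset head velocity above pre-onset, same sign
  expect_gt(abs(pp[["post_head"]]), abs(pp[["pre_head"]]))
  expect_equal(sign(pp[["post_head"]]), sign(pp[["pre_head"]]))
  expect_true(classify_head_lead(ev[1, ]))

  eyelead <- shift_record(60, sim_config(head_lead = -0.05))
  ev2 <- detect_gaze_saccades(eyelead$rec)
  pp2 <- pre_post_velocities(eyelead$rec, ev2[1, ])
  expect_lt(abs(pp2[["pre_head"]]), 1)  # head stationary before the saccade
  expect_false(classify_head_lead(ev2[1, ]))
})

test_that("classify_head_lead applies the velocity rule", {
  expect_true(classify_head_lead(
    data.frame(pre_head_vel_dps = 20, post_head_vel_dps = 120)))
  expect_false(classify_head_lead(
    data.frame(pre_head_vel_dps = 0.5, post_head_vel_dps = 120)))
  expect_false(classify_head_lead(
    data.frame(pre_head_vel_dps = -20, post_head_vel_dps = 120)))
})

test_that("detected amplitude is monotone in simulated amplitude", {
  amps <- c(20, 40, 80, 120, 143)
  det <- vapply(amps, function(a) {
    detect_gaze_saccades(shift_record(a)$rec)$gaze_amplitude_deg[1]
  }, numeric(1))
  expect_true(all(diff(det) > 0))
})

test_that("coordination_summary aggregates per condition and finds structure", {
  # identical synthetic events: zero standard errors
  ev <- do.call(rbind, replicate(6, {
    e <- detect_gaze_saccades(shift_record(90)$rec)
    e$condition <- "90"
    e
  }, simplify = FALSE))
  ev2 <- detect_gaze_saccades(shift_record(40)$rec)
  ev2$condition <- "40"
  all_ev <- rbind(ev, ev2[rep(1, 3), ])
  class(all_ev) <- c("gaze_shift_events", "data.frame")
  s <- coordination_summary(all_ev)
  expect_equal(s$per_condition$gaze_amplitude_sem,
               c(0, 0), tolerance = 1e-9)
  expect_equal(s$head_leads_fraction, 1)

  expect_error(coordination_summary(all_ev[1:7, ], min_events = 3),
               "too few")
  expect_error(coordination_summary(ev), "2 conditions")
})

test_that("summary flags sublinear saccade contribution and recovers the slope", {
  cfg <- sim_config()
  conds <- c(38.3, 91.2, 143.6)
  evs <- lapply(conds, function(a) {
    e <- detect_gaze_saccades(shift_record(a, cfg)$rec)
    e <- e[rep(1, 3), ]
    e$condition <- sprintf("%.1f", a)
    e
  })
  all_ev <- do.call(rbind, evs)
  class(all_ev) <- c("gaze_shift_events", "data.frame")
  s <- coordination_summary(all_ev)
  expect_true(s$saccade_sublinear)
  expect_equal(s$head_velocity_slope_per_s, cfg$head_velocity_slope,
               tolerance = 0.1)
  # per-condition table is ordered by measured gaze amplitude
  expect_equal(s$per_condition$condition, sprintf("%.1f", conds))
})

test_that("records without velocity channels are rejected", {
  rec <- record_from_truth(list(list(type = "fixation", t0 = 0, dur = 2,
                                     e0 = 0, h0 = 0)))
  rec$dG_dps <- NULL
  expect_error(detect_gaze_saccades(rec), "velocity")
})
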