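#' Simulator configuration
#'
#' Parameters of the kinematic eye-head gaze-shift generator. Defaults state
#' the measurement protocol being emulated: six target-separation conditions
#' from 17.6 to 143.6 degrees, 45 self-paced alternating shifts per
#' condition, a 23-fixation calibration sweep, head-oscillation
#' synchronization episodes before/between/after conditions, an eye stream
#' with the bimodal 4/8-ms sample-interval mixture calibrated to a 200.54-Hz
#' effective rate, and a 250-Hz head camera stream.
#'
#' @param target_separations Degrees between target pairs per condition.
#' @param shifts_per_condition Alternating shifts per condition.
#' @param head_lead Seconds the head movement starts before the saccade
#'   (negative = eye leads).
#' @param head_velocity_slope Peak head velocity per degree of gaze
#'   amplitude, 1/s.
#' @param saccade_vmax,saccade_a63 Main-sequence parameters of
#'   `V_peak = V_max (1 - exp(-A / A_63))` (deg/s and deg).
#' @param saccade_amplitude_cap Physical saccade-amplitude limit, degrees.
#' @param share_kink,share_slope Eye-head amplitude sharing: the saccade
#'   carries `A (1 - 0.1 A / kink)` of a gaze amplitude `A` up to the kink,
#'   and a `share_slope` marginal share beyond it (capped), so its relative
#'   contribution shrinks for larger gaze shifts.
#' @param vor_gain Vestibulo-ocular counter-rotation gain outside saccades.
#' @param eye_noise_sd,head_noise_sd Additive Gaussian angle noise, degrees.
#' @param eye_interval_modes,eye_interval_sds Bimodal eye sample-interval
#'   mixture components, seconds.
#' @param eye_effective_rate Target effective frequency, Hz; fixes the
#'   mixture weights.
#' @param head_rate Head camera frame rate, Hz.
#' @param calibration_constant_true True additive gaze constant c, degrees
#'   (realized as a scene-camera mounting bias of -c on E).
#' @param sync_offset_true Seconds the eye clock runs ahead of the head
#'   clock.
#' @param oculomotor_range Mechanical eye-in-head limit, degrees.
#' @param marker_yaw0,marker_pitch,marker_roll Marker mounting angles on the
#'   head, degrees (yaw0 is the arbitrary zero removed by the reference
#'   fixation).
#' @param marker_translation Marker position in the ceiling-camera frame,
#'   meters.
#' @param marker_side Marker side length, meters.
#' @param osc_amplitude,osc_frequency,osc_cycles Head-oscillation episode
#'   shape (degrees, Hz, count).
#' @param fixation_pause Pause between shifts, seconds.
#' @param calib_fix_duration Calibration fixation duration, seconds.
#' @param transition_velocity Peak gaze velocity of slow between-block
#'   transitions, deg/s (kept below the saccade detection threshold).
#' @param seed Integer seed; identical configs produce identical sessions.
#' @return A `sim_config` list.
#' @export
sim_config <- function(target_separations = c(17.6, 38.3, 63.3, 91.2, 118.9, 143.6),
                       shifts_per_condition = 45,
                       head_lead = 0.08,
                       head_velocity_slope = 2.31,
                       saccade_vmax = 500, saccade_a63 = 14,
                       saccade_amplitude_cap = 80,
                       share_kink = 35, share_slope = 0.38,
                       vor_gain = 1.0,
                       eye_noise_sd = 0.05, head_noise_sd = 0.02,
                       eye_interval_modes = c(0.004, 0.008),
                       eye_interval_sds = c(8e-5, 8e-5),
                       eye_effective_rate = 200.54,
                       head_rate = 250,
                       calibration_constant_true = 1.2,
                       sync_offset_true = 0.2,
                       oculomotor_range = 40,
                       marker_yaw0 = 20, marker_pitch = 2, marker_roll = 1,
                       marker_translation = c(0.05, -0.03, 1.0),
                       marker_side = 0.1,
                       osc_amplitude = 6, osc_frequency = 2.5, osc_cycles = 8,
                       fixation_pause = 1.0,
                       calib_fix_duration = 1.5,
                       transition_velocity = 35,
                       seed = 1L) {
  stopifnot(all(target_separations > 0), all(target_separations < 220),
            saccade_amplitude_cap <= 80, shifts_per_condition >= 1,
            head_velocity_slope >= 0, vor_gain >= 0,
            length(eye_interval_modes) == 2)
  mean_int <- 1 / eye_effective_rate
  w1 <- (eye_interval_modes[2] - mean_int) /
    (eye_interval_modes[2] - eye_interval_modes[1])
  if (w1 <= 0 || w1 >= 1) {
    stop("eye_effective_rate is not reachable with the given interval modes")
  }
  cfg <- list(
    target_separations = target_separations,
    shifts_per_condition = shifts_per_condition,
    head_lead = head_lead,
    head_velocity_slope = head_velocity_slope,
    saccade_vmax = saccade_vmax, saccade_a63 = saccade_a63,
    saccade_amplitude_cap = saccade_amplitude_cap,
    share_kink = share_kink, share_slope = share_slope,
    vor_gain = vor_gain,
    eye_noise_sd = eye_noise_sd, head_noise_sd = head_noise_sd,
    eye_interval_modes = eye_interval_modes,
    eye_interval_sds = eye_interval_sds,
    eye_interval_weights = c(w1, 1 - w1),
    eye_effective_rate = eye_effective_rate,
    head_rate = head_rate,
    calibration_constant_true = calibration_constant_true,
    sync_offset_true = sync_offset_true,
    oculomotor_range = oculomotor_range,
    marker_yaw0 = marker_yaw0, marker_pitch = marker_pitch,
    marker_roll = marker_roll,
    marker_translation = marker_translation, marker_side = marker_side,
    osc_amplitude = osc_amplitude, osc_frequency = osc_frequency,
    osc_cycles = osc_cycles,
    fixation_pause = fixation_pause,
    calib_fix_duration = calib_fix_duration,
    transition_velocity = transition_velocity,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# ---- raised-cosine (bell) velocity primitives -------------------------------
# displacement fraction of a bell of duration D at local time u (clipped)
bell_frac <- function(u, D) {
  if (D <= 0) return(rep(1, length(u)))  # degenerate: movement complete
  u <- pmin(pmax(u, 0), D)
  u / D - sin(2 * pi * u / D) / (2 * pi)
}
# velocity of a bell with total displacement A and duration D (peak 2A/D)
bell_vel <- function(u, A, D) {
  if (D <= 0) return(rep(0, length(u)))
  v <- (A / D) * (1 - cos(2 * pi * u / D))
  v[u < 0 | u > D] <- 0
  v
}

# main-sequence peak velocity for a saccade amplitude
mainseq_vpeak <- function(A, cfg) cfg$saccade_vmax * (1 - exp(-A / cfg$saccade_a63))

# eye-head amplitude sharing: saccade amplitude for a gaze amplitude
saccade_share <- function(Ag, cfg) {
  k <- cfg$share_kink
  a <- ifelse(Ag <= k, Ag * (1 - 0.1 * Ag / k),
              0.9 * k + cfg$share_slope * (Ag - k))
  pmin(a, cfg$saccade_amplitude_cap)
}

# ---- gaze-shift kinematic plan ---------------------------------------------
# VOR weight during a shift: 1 outside the saccade, 0 in its core, with
# short cosine ramps just inside the saccade boundaries. The smooth
# deactivation avoids a velocity discontinuity at saccade onset (VOR
# suppression is not instantaneous), which keeps the 10%-of-peak onset
# landmark well defined for truth and detector alike.
vor_weight <- function(u, ts0, ts1, r) {
  w <- numeric(length(u))
  w[u <= ts0 | u >= ts1] <- 1
  i <- u > ts0 & u < ts0 + r
  w[i] <- (1 + cos(pi * (u[i] - ts0) / r)) / 2
  j <- u > ts1 - r & u < ts1
  w[j] <- (1 - cos(pi * (u[j] - (ts1 - r)) / r)) / 2
  w
}

# cumulative trapezoid
cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (y[-1] + y[-length(y)]) / 2))

# Solves the head-bell duration so the shift closes exactly at the requested
# gaze amplitude. With eye velocity dE = vs - g w vh (vs the saccade bell,
# vh the head bell, w the VOR weight), the gaze displacement is
# Ag = A_sacc + g I + (1 - g) H_total, where I = int (1 - w) vh du is the
# effectively uncompensated head displacement inside the saccade. The
# smaller of the two candidate durations is used, which keeps post-saccadic
# head movement (and hence eye-in-head eccentricity) small for the largest
# shifts.
plan_gaze_shift <- function(Ag, cfg) {
  stopifnot(Ag > 0)
  g <- cfg$vor_gain
  L <- cfg$head_lead
  Vh <- cfg$head_velocity_slope * Ag
  if (Vh == 0) {
    # degenerate head-free case: the eye alone carries the shift
    A_sacc <- Ag
    if (A_sacc > cfg$saccade_amplitude_cap) {
      stop("unreachable amplitude: ", Ag,
           " deg requires a saccade above the amplitude cap with a flat head")
    }
    Vs <- mainseq_vpeak(A_sacc, cfg)
    Ds <- 2 * A_sacc / Vs
    ts0 <- max(0, L)
    return(list(Ag = Ag, A_sacc = A_sacc, A_sacc_eye = A_sacc, Ds = Ds,
                Vs = Vs, Vh = 0, Dh = 0, th0 = 0, ts0 = ts0, H_total = 0,
                H_pre = 0, H_sacc = 0, H_post = 0, dE_net = A_sacc,
                vor_ramp = 0, j_t = c(ts0, ts0 + Ds), j_v = c(0, 0),
                t_end = ts0 + Ds, g = g, L = L))
  }
  th0 <- max(0, -L)   # local segment time of head-movement start
  ts0 <- max(0, L)    # local segment time of saccade start
  closure_for <- function(A_sacc) {
    Ds <- 2 * A_sacc / mainseq_vpeak(A_sacc, cfg)
    ts1 <- ts0 + Ds
    r <- min(0.015, Ds / 4)
    uq <- seq(ts0, ts1, length.out = 257)
    wq <- 1 - vor_weight(uq, ts0, ts1, r)
    function(Dh) {
      H_total <- Vh * Dh / 2
      vh <- bell_vel(uq - th0, H_total, Dh)
      I <- sum(diff(uq) * (wq[-1] * vh[-1] + wq[-257] * vh[-257]) / 2)
      A_sacc + g * I + (1 - g) * H_total - Ag
    }
  }
  grid <- exp(seq(log(0.02), log(8), length.out = 400))
  best <- function(A_sacc) max(vapply(grid, closure_for(A_sacc), numeric(1)))
  A_sacc <- saccade_share(Ag, cfg)
  if (best(A_sacc) < 0.5) {
    # share-rule saccade too small for the head bell (peak velocity pinned
    # at slope * Ag) to close the shift within the saccade window: raise the
    # saccade amplitude to the smallest achievable value plus a margin.
    A_hi <- min(cfg$saccade_amplitude_cap, Ag)
    if (best(A_hi) < 0.5) {
      stop("unreachable amplitude: ", Ag, " deg exceeds the achievable ",
           "eye + head contribution under the configured kinematics")
    }
    A_sacc <- stats::uniroot(function(a) best(a) - 0.5, c(A_sacc, A_hi),
                             tol = 1e-9)$root
  }
  Vs <- mainseq_vpeak(A_sacc, cfg)
  Ds <- 2 * A_sacc / Vs
  ts1 <- ts0 + Ds
  vor_ramp <- min(0.015, Ds / 4)
  closure <- closure_for(A_sacc)
  fg <- vapply(grid, closure, numeric(1))
  ix <- which(fg[-1] >= 0 & fg[-length(fg)] < 0)[1]
  if (is.na(ix)) ix <- 1
  Dh <- stats::uniroot(closure, c(grid[ix], grid[ix + 1]), tol = 1e-12)$root
  H_total <- Vh * Dh / 2
  # dense cumulative integral J(u) = int_ts0^u (1 - w) vh, for segment eval
  uj <- seq(ts0, ts1, length.out = 1025)
  integrand <- (1 - vor_weight(uj, ts0, ts1, vor_ramp)) *
    bell_vel(uj - th0, H_total, Dh)
  jv <- cumtrapz(uj, integrand)
  I_total <- jv[length(jv)]
  H_pre <- H_total * bell_frac(ts0 - th0, Dh)
  H_sacc <- H_total * (bell_frac(ts1 - th0, Dh) - bell_frac(ts0 - th0, Dh))
  H_post <- H_total - H_pre - H_sacc
  dE_net <- A_sacc - g * (H_total - I_total)
  list(Ag = Ag, A_sacc = A_sacc,
       A_sacc_eye = A_sacc - g * (H_sacc - I_total),  # eye displacement over the saccade
       Ds = Ds, Vs = Vs, Vh = Vh, Dh = Dh,
       th0 = th0, ts0 = ts0, H_total = H_total, H_pre = H_pre,
       H_sacc = H_sacc, H_post = H_post, dE_net = dE_net,
       vor_ramp = vor_ramp, j_t = uj, j_v = jv,
       t_end = max(th0 + Dh, ts0 + Ds), g = g, L = L)
}

# ---- segment evaluation -----------------------------------------------------
# A session is a contiguous list of segments; each knows its absolute start
# time, duration, entry state (e0, h0) and type-specific parameters. eval
# functions return absolute E, H and their time derivatives at local time u.

seg_eval <- function(seg, u) {
  switch(seg$type,
    fixation = list(E = rep(seg$e0, length(u)), H = rep(seg$h0, length(u)),
                    dE = numeric(length(u)), dH = numeric(length(u))),
    ramp = {
      s <- bell_frac(u, seg$dur)
      ds <- bell_vel(u, 1, seg$dur)
      list(E = seg$e0 + seg$dE_total * s, H = seg$h0 + seg$dH_total * s,
           dE = seg$dE_total * ds, dH = seg$dH_total * ds)
    },
    oscillation = {
      D <- seg$dur; A <- seg$amp; f <- seg$freq; g <- seg$gain
      env <- (1 - cos(2 * pi * u / D)) / 2
      denv <- pi / D * sin(2 * pi * u / D)
      h <- A * sin(2 * pi * f * u) * env
      dh <- A * (2 * pi * f * cos(2 * pi * f * u) * env +
                   sin(2 * pi * f * u) * denv)
      list(E = seg$e0 - g * h, H = seg$h0 + h, dE = -g * dh, dH = dh)
    },
    shift = {
      p <- seg$plan; sgn <- seg$dir
      ts1 <- p$ts0 + p$Ds
      hb <- p$H_total * bell_frac(u - p$th0, p$Dh)
      sac <- p$A_sacc * bell_frac(u - p$ts0, p$Ds)
      vh <- bell_vel(u - p$th0, p$H_total, p$Dh)
      vs <- bell_vel(u - p$ts0, p$A_sacc, p$Ds)
      w <- vor_weight(u, p$ts0, ts1, p$vor_ramp)
      # J(u): head displacement inside the saccade not VOR-compensated
      J <- stats::approx(p$j_t, p$j_v, xout = pmin(pmax(u, p$ts0), ts1),
                         rule = 2)$y
      list(E = seg$e0 + sgn * (sac - p$g * (hb - J)),
           H = seg$h0 + sgn * hb,
           dE = sgn * (vs - p$g * w * vh),
           dH = sgn * vh)
    },
    stop("unknown segment type: ", seg$type))
}

# evaluate a segment list at absolute times t (any order)
segments_eval <- function(segments, t) {
  starts <- vapply(segments, `[[`, numeric(1), "t0")
  ends <- vapply(segments, function(s) s$t0 + s$dur, numeric(1))
  idx <- findInterval(pmin(pmax(t, starts[1]), ends[length(ends)]), starts,
                      rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  E <- H <- dE <- dH <- numeric(length(t))
  for (k in unique(idx)) {
    sel <- idx == k
    u <- pmin(t[sel] - segments[[k]]$t0, segments[[k]]$dur)
    r <- seg_eval(segments[[k]], u)
    E[sel] <- r$E; H[sel] <- r$H; dE[sel] <- r$dE; dH[sel] <- r$dH
  }
  data.frame(t = t, E = E, H = H, G = E + H, dE = dE, dH = dH,
             dG = dE + dH)
}

#' Evaluate the simulator's ground truth at arbitrary times
#'
#' @param truth The `truth` element returned by [simulate_session()] (or by
#'   [simulate_gaze_shift()] / [simulate_oscillation()]).
#' @param t Times in seconds (head clock).
#' @return Data frame `t, E, H, G, dE, dH, dG` (degrees, deg/s); `G` includes
#'   the true calibration constant so it is world-fixed gaze.
#' @export
truth_eval <- function(truth, t) {
  out <- segments_eval(truth$segments, t)
  out$G <- out$G  # E + H already world-fixed in the truth parameterization
  out
}

# end state of a segment
seg_end_state <- function(seg) {
  r <- seg_eval(seg, seg$dur)
  c(e = unname(r$E[1]), h = unname(r$H[1]))
}

# 10%-of-peak gaze-velocity landmarks of a shift segment, by fine scanning.
# These are the ground-truth counterparts of the detector's refined
# onset/offset (which refine to 10% of the event's peak gaze velocity).
shift_landmarks <- function(seg, frac = 0.1, dt = 5e-4) {
  u <- seq(0, seg$dur, by = dt)
  r <- seg_eval(seg, u)
  dG <- r$dE + r$dH
  pk <- max(abs(dG))
  above <- which(abs(dG) >= frac * pk)
  i0 <- above[1]; i1 <- above[length(above)]
  G <- r$E + r$H
  c(onset = seg$t0 + u[i0], offset = seg$t0 + u[i1],
    peak_gaze_velocity = pk,
    gaze_amplitude_land = abs(G[i1] - G[i0]),
    saccade_amplitude_land = abs(r$E[i1] - r$E[i0]))
}

#' Simulate a single combined eye-head gaze shift
#'
#' Builds the kinematic plan for one gaze shift of the requested amplitude
#' (head bell with peak velocity `head_velocity_slope * amplitude`, saccade
#' bell following the main sequence, VOR counter-rotation outside the
#' saccade) and evaluates the noise-free truth on a fine grid.
#'
#' @param amplitude Gaze-shift amplitude in degrees (> 0).
#' @param config A [sim_config()].
#' @param direction +1 (leftward) or -1 (rightward).
#' @param e0,h0 Initial eye-in-head and head angles, degrees; defaults place
#'   the eye at the stationary alternation offset.
#' @param rate Trace sampling rate, Hz.
#' @return List with `plan` (kinematic scalars), `trace` (data frame
#'   `t, E, H, G, dE, dH, dG`), `event` (true landmark row) and `segments`
#'   (for [truth_eval()]).
#' @export
simulate_gaze_shift <- function(amplitude, config = sim_config(),
                                direction = 1, e0 = NULL, h0 = 0,
                                rate = 1000) {
  plan <- plan_gaze_shift(amplitude, config)
  if (is.null(e0)) e0 <- -direction * plan$dE_net / 2
  pad <- 0.3
  seg <- list(type = "shift", t0 = pad, dur = plan$t_end, e0 = e0, h0 = h0,
              plan = plan, dir = direction)
  pre <- list(type = "fixation", t0 = 0, dur = pad, e0 = e0, h0 = h0)
  endst <- seg_end_state(seg)
  post <- list(type = "fixation", t0 = pad + plan$t_end, dur = pad,
               e0 = endst["e"], h0 = endst["h"])
  segments <- list(pre, seg, post)
  lm <- shift_landmarks(seg)
  tt <- seq(0, 2 * pad + plan$t_end, by = 1 / rate)
  trace <- segments_eval(segments, tt)
  event <- data.frame(
    t_onset = lm[["onset"]], t_offset = lm[["offset"]],
    t_saccade_start = pad + plan$ts0,
    t_saccade_end = pad + plan$ts0 + plan$Ds,
    gaze_amplitude = plan$Ag, saccade_amplitude = plan$A_sacc_eye,
    head_during_saccade = plan$H_sacc, head_total = plan$H_total,
    peak_saccade_velocity = plan$Vs, peak_head_velocity = plan$Vh,
    peak_gaze_velocity = lm[["peak_gaze_velocity"]],
        gaze_amplitude_land = lm[["gaze_amplitude_land"]],
        saccade_amplitude_land = lm[["saccade_amplitude_land"]],
    direction = direction)
  list(plan = plan, trace = trace, event = event,
       segments = segments)
}

#' Simulate a head-oscillation synchronization episode
#'
#' Sinusoidal head yaw under a raised-cosine envelope while the participant
#' fixates, so the eye counter-rotates at the fixation VOR gain of 1 and
#' E + H stays constant.
#'
#' @param duration Episode duration in seconds (defaults to
#'   `osc_cycles / osc_frequency`).
#' @param frequency Oscillation frequency, Hz.
#' @param amplitude Peak head amplitude, degrees.
#' @param config A [sim_config()].
#' @param rate Trace sampling rate, Hz.
#' @return List with `trace` and `segments`.
#' @export
simulate_oscillation <- function(duration = NULL,
                                 frequency = NULL, amplitude = NULL,
                                 config = sim_config(), rate = 1000) {
  if (is.null(frequency)) frequency <- config$osc_frequency
  if (is.null(amplitude)) amplitude <- config$osc_amplitude
  if (is.null(duration)) duration <- config$osc_cycles / frequency
  seg <- list(type = "oscillation", t0 = 0, dur = duration, e0 = 0, h0 = 0,
              amp = amplitude, freq = frequency, gain = 1)
  tt <- seq(0, duration, by = 1 / rate)
  list(trace = segments_eval(list(seg), tt), segments = list(seg))
}

# ---- session assembly -------------------------------------------------------

# append a slow (sub-detection-threshold) transition + optional fixation
add_ramp <- function(segments, state, tcur, dE_total, dH_total, vmax) {
  dG <- abs(dE_total + dH_total)
  dur <- max(0.6, 2 * dG / vmax)
  seg <- list(type = "ramp", t0 = tcur, dur = dur, e0 = state["e"],
              h0 = state["h"], dE_total = dE_total, dH_total = dH_total)
  segments[[length(segments) + 1]] <- seg
  list(segments = segments, state = state + c(dE_total, dH_total),
       t = tcur + dur)
}

add_fixation <- function(segments, state, tcur, dur) {
  segments[[length(segments) + 1]] <-
    list(type = "fixation", t0 = tcur, dur = dur, e0 = state["e"],
         h0 = state["h"])
  list(segments = segments, state = state, t = tcur + dur)
}

#' Simulate a full recording session
#'
#' Generates the complete protocol: a zero fixation (head-orientation
#' reference), the 23-fixation calibration sweep over the 12 wall targets,
#' head-oscillation episodes before, between and after the six
#' target-separation conditions, and the alternating gaze shifts of each
#' condition. Head yaw is rendered as marker poses projected to ceiling-
#' camera corner pixels; eye angles are inverted through the scene camera's
#' tangent mapping to pixels, timestamped with the bimodal interval mixture
#' and shifted by the true clock offset. Gaussian angle noise is added per
#' the configuration.
#'
#' Between-block transitions are slow gaze movements with peak velocity
#' below the saccade detection threshold, so the detected events are exactly
#' the per-condition shifts.
#'
#' @param config A [sim_config()].
#' @return List with `markers` (ceiling-camera corner table), `eye`
#'   (eye-tracker sample table), `targets` (calibration windows + azimuths)
#'   and `truth` (segments, true event table, condition/oscillation windows,
#'   true c, true sync offset, cameras, config).
#' @export
simulate_session <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scene <- scene_camera()
  ceiling <- ceiling_camera()
  segments <- list()
  state <- c(e = 0, h = 0)
  tcur <- 0
  events <- list()
  cond_windows <- list()
  osc_windows <- list()
  calib_windows <- list()

  # 1. zero fixation at the room corner: head reference and gaze zero
  r <- add_fixation(segments, state, tcur, 2.0)
  segments <- r$segments; tcur <- r$t
  reference_window <- c(0.2, 1.8)

  # 2. calibration sweep: 12 targets right to left, then back (23 fixations)
  seps <- sort(config$target_separations)
  targets12 <- sort(c(-seps / 2, seps / 2))  # world azimuths, positive = left
  # rightmost (most negative azimuth) to leftmost, then back: 12 + 11 = 23
  sweep <- c(targets12, rev(targets12)[-1])
  for (tg in sweep) {
    tg_e <- 0.2 * tg; tg_h <- 0.8 * tg
    r <- add_ramp(segments, state, tcur, tg_e - state["e"], tg_h - state["h"],
                  config$transition_velocity)
    segments <- r$segments; state <- r$state; tcur <- r$t
    calib_windows[[length(calib_windows) + 1]] <-
      data.frame(t0 = tcur, t1 = tcur + config$calib_fix_duration,
                 azimuth_deg = tg)
    r <- add_fixation(segments, state, tcur, config$calib_fix_duration)
    segments <- r$segments; tcur <- r$t
  }

  add_oscillation <- function(segments, state, tcur) {
    r <- add_ramp(segments, state, tcur, -state["e"], -state["h"],
                  config$transition_velocity)
    segments <- r$segments; state <- r$state; tcur <- r$t
    dur <- config$osc_cycles / config$osc_frequency
    segments[[length(segments) + 1]] <-
      list(type = "oscillation", t0 = tcur, dur = dur, e0 = state["e"],
           h0 = state["h"], amp = config$osc_amplitude,
           freq = config$osc_frequency, gain = 1)
    list(segments = segments, state = state, t = tcur + dur,
         window = c(tcur, tcur + dur))
  }

  r <- add_oscillation(segments, state, tcur)
  segments <- r$segments; state <- r$state; tcur <- r$t
  osc_windows[[length(osc_windows) + 1]] <- r$window

  # 3. six conditions of alternating shifts, oscillations in between
  for (sep in config$target_separations) {
    plan <- plan_gaze_shift(sep, config)
    dir1 <- -1  # first shift: left target (+sep/2) to right target (-sep/2)
    e_start <- -dir1 * plan$dE_net / 2
    h_start <- dir1 * -sep / 2 - e_start
    r <- add_ramp(segments, state, tcur, e_start - state["e"],
                  h_start - state["h"], config$transition_velocity)
    segments <- r$segments; state <- r$state; tcur <- r$t
    r <- add_fixation(segments, state, tcur, 1.0)
    segments <- r$segments; tcur <- r$t
    cond_t0 <- tcur
    dir <- dir1
    for (k in seq_len(config$shifts_per_condition)) {
      seg <- list(type = "shift", t0 = tcur, dur = plan$t_end,
                  e0 = state["e"], h0 = state["h"], plan = plan, dir = dir)
      segments[[length(segments) + 1]] <- seg
      lm <- shift_landmarks(seg)
      events[[length(events) + 1]] <- data.frame(
        condition = sep,
        t_onset = lm[["onset"]], t_offset = lm[["offset"]],
        t_saccade_start = tcur + plan$ts0,
        t_saccade_end = tcur + plan$ts0 + plan$Ds,
        gaze_amplitude = plan$Ag, saccade_amplitude = plan$A_sacc_eye,
        head_during_saccade = plan$H_sacc, head_total = plan$H_total,
        peak_saccade_velocity = plan$Vs, peak_head_velocity = plan$Vh,
        peak_gaze_velocity = lm[["peak_gaze_velocity"]],
        gaze_amplitude_land = lm[["gaze_amplitude_land"]],
        saccade_amplitude_land = lm[["saccade_amplitude_land"]],
        direction = dir)
      endst <- seg_end_state(seg)
      state <- c(e = unname(endst["e"]), h = unname(endst["h"]))
      tcur <- tcur + plan$t_end
      r <- add_fixation(segments, state, tcur, config$fixation_pause)
      segments <- r$segments; tcur <- r$t
      dir <- -dir
    }
    cond_windows[[length(cond_windows) + 1]] <-
      data.frame(t0 = cond_t0 - 0.3, t1 = tcur, condition = sep)
    r <- add_oscillation(segments, state, tcur)
    segments <- r$segments; state <- r$state; tcur <- r$t
    osc_windows[[length(osc_windows) + 1]] <- r$window
  }
  r <- add_fixation(segments, state, tcur, 1.0)
  segments <- r$segments; tcur <- r$t
  T_end <- tcur

  # ---- render the eye-tracker stream ---------------------------------------
  # The interval mixture is constructed to the requested effective rate:
  # long intervals are laid out by cumulative rounding (so every prefix of
  # the stream carries the target fraction to within one block) and then
  # shuffled locally, which keeps the realized effective frequency within
  # ~0.01 Hz of the target instead of wobbling with a Bernoulli sum.
  n_base <- ceiling(T_end * config$eye_effective_rate)
  n_guess <- n_base + max(200, ceiling(0.02 * n_base))
  w2 <- config$eye_interval_weights[2]
  comp <- 1L + (floor(seq_len(n_guess) * w2) -
                  floor((seq_len(n_guess) - 1) * w2))
  blk <- (seq_len(n_guess) - 1) %/% 20
  comp <- unlist(lapply(unname(split(comp, blk)),
                        function(x) x[sample.int(length(x))]),
                 use.names = FALSE)
  ints <- stats::rnorm(n_guess, config$eye_interval_modes[comp],
                       config$eye_interval_sds[comp])
  t_eye <- cumsum(ints)
  t_eye <- t_eye[t_eye < T_end]
  tr <- segments_eval(segments, t_eye)
  bias <- -config$calibration_constant_true
  az <- tr$E + bias + stats::rnorm(length(t_eye), 0, config$eye_noise_sd)
  px <- angles_to_pixels(az, 0, scene)
  out_of_frame <- px$x_px < 0 | px$x_px > scene$width
  if (any(out_of_frame)) {
    warning(sum(out_of_frame),
            " simulated gaze points fall outside the scene image")
  }
  eye <- data.frame(timestamp = t_eye + config$sync_offset_true,
                    x_px = px$x_px, y_px = px$y_px, valid = 1L)

  # ---- render the ceiling-camera marker stream -----------------------------
  t_head <- seq(0, T_end, by = 1 / config$head_rate)
  trh <- segments_eval(segments, t_head)
  psi <- config$marker_yaw0 + trh$H +
    stats::rnorm(length(t_head), 0, config$head_noise_sd)
  mk <- marker_model(config$marker_side)
  tilt <- rot_y(config$marker_pitch * pi / 180) %*%
    rot_x(config$marker_roll * pi / 180)
  q <- tilt %*% t(mk$corners)                       # 3 x 4 tilted corners
  tv <- config$marker_translation
  cs <- cos(psi * pi / 180); sn <- sin(psi * pi / 180)
  f <- ceiling$focal_length; pp <- ceiling$principal_point
  corner_px <- matrix(NA_real_, length(t_head), 8)
  for (j in 1:4) {
    X <- cs * q[1, j] - sn * q[2, j] + tv[1]
    Y <- sn * q[1, j] + cs * q[2, j] + tv[2]
    Z <- q[3, j] + tv[3]
    corner_px[, 2 * j - 1] <- f * X / Z + pp[1]
    corner_px[, 2 * j] <- f * Y / Z + pp[2]
  }
  markers <- data.frame(timestamp = t_head,
                        x0 = corner_px[, 1], y0 = corner_px[, 2],
                        x1 = corner_px[, 3], y1 = corner_px[, 4],
                        x2 = corner_px[, 5], y2 = corner_px[, 6],
                        x3 = corner_px[, 7], y3 = corner_px[, 8],
                        valid = 1L)

  targets <- do.call(rbind, calib_windows)
  truth <- list(
    config = config,
    segments = segments,
    events = do.call(rbind, events),
    condition_windows = do.call(rbind, cond_windows),
    oscillation_windows = {
      ow <- do.call(rbind, osc_windows)
      data.frame(t0 = ow[, 1], t1 = ow[, 2])
    },
    calibration_windows = targets,
    reference_window = reference_window,
    c_true = config$calibration_constant_true,
    sync_offset_true = config$sync_offset_true,
    duration = T_end,
    scene_camera = scene, ceiling_camera = ceiling,
    marker = mk)
  list(markers = markers, eye = eye, targets = targets, truth = truth)
}
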