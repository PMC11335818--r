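#' Detect gaze saccades in a fused record
#'
#' Candidate events are intervals where the absolute gaze velocity |dG|
#' exceeds `high_threshold`; onset and offset are then refined outward to the
#' samples where |dG| first falls below `refine_fraction` of that event's
#' peak velocity. Events separated by less than `merge_gap_s` are merged, and
#' events with gaze amplitude below `min_amplitude` are discarded. Gaze
#' velocity (not eye velocity) is thresholded because the vestibulo-ocular
#' reflex holds dG near zero outside saccades, so gaze velocity isolates the
#' saccadic phase of a combined eye-head shift.
#'
#' Detection, peak measurement and boundary refinement use a 5-sample
#' local-quadratic (Savitzky-Golay) smoothed velocity, which suppresses
#' sample noise without biasing the bell-shaped velocity profiles; the
#' refinement walk tolerates single-sample dips below threshold.
#'
#' @param record A `gaze_record` with velocity channels ([fuse()]).
#' @param high_threshold Detection threshold, deg/s (default 50).
#' @param refine_fraction Boundary refinement fraction of the event peak
#'   (default 0.1).
#' @param merge_gap_s Events closer than this are merged (default 0.05 s).
#' @param min_amplitude Minimum |gaze amplitude| in degrees (default 5).
#' @param min_above_samples Minimum consecutive samples above
#'   `high_threshold` for a candidate (default 3); rejects single-sample
#'   noise spikes that would otherwise seed an event on top of slow gaze
#'   movements.
#' @param condition_windows Optional data frame `t0, t1, condition` used to
#'   label each event with the experimental condition containing its onset.
#' @return A `gaze_shift_events` data frame, one row per event, with the
#'   saccade interval, amplitudes (signed displacements in `*_displacement`
#'   columns, magnitudes in `*_amplitude`), peak velocities, durations, VOR
#'   phase bounds and gain, pre/post 100-ms window velocities, and the
#'   head-lead classification.
#' @export
detect_gaze_saccades <- function(record, high_threshold = 50,
                                 refine_fraction = 0.1, merge_gap_s = 0.05,
                                 min_amplitude = 5,
                                 min_above_samples = 3,
                                 condition_windows = NULL) {
  stopifnot(inherits(record, "gaze_record"))
  if (!all(c("dG_dps", "dE_dps", "dH_dps") %in% names(record))) {
    stop("record has no velocity channels; build it with fuse()")
  }
  rate <- attr(record, "rate_hz")
  dt <- 1 / rate
  n <- nrow(record)
  vg_s <- estimate_velocity(record$G_deg, dt, "sgolay")
  vg_s[!record$valid] <- 0
  above <- abs(vg_s) > high_threshold
  if (!any(above)) return(empty_events())

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- cbind(starts[r$values], ends[r$values])
  # minimum-duration criterion: a real saccade stays above threshold for
  # many samples, a noise spike does not
  cand <- cand[cand[, 2] - cand[, 1] + 1 >= min_above_samples, ,
               drop = FALSE]
  if (!nrow(cand)) return(empty_events())

  # merge candidates closer than merge_gap_s
  merged <- list()
  cur <- cand[1, ]
  for (i in seq_len(nrow(cand))[-1]) {
    if ((cand[i, 1] - cur[2]) * dt < merge_gap_s) cur[2] <- cand[i, 2]
    else { merged[[length(merged) + 1]] <- cur; cur <- cand[i, ] }
  }
  merged[[length(merged) + 1]] <- cur

  rows <- lapply(merged, function(iv) {
    i0 <- iv[1]; i1 <- iv[2]
    pk <- max(abs(vg_s[i0:i1]))
    thr <- refine_fraction * pk
    # walk outward while the velocity (or its neighbour, to ride out single
    # noise dips) is still above the refinement threshold
    while (i0 > 1 && (abs(vg_s[i0 - 1]) >= thr ||
                      (i0 > 2 && abs(vg_s[i0 - 2]) >= thr))) i0 <- i0 - 1
    while (i1 < n && (abs(vg_s[i1 + 1]) >= thr ||
                      (i1 < n - 1 && abs(vg_s[i1 + 2]) >= thr))) i1 <- i1 + 1
    # sub-sample threshold crossings by linear interpolation
    t_on <- record$time[i0]
    if (i0 > 1 && abs(vg_s[i0]) > abs(vg_s[i0 - 1])) {
      fr <- (abs(vg_s[i0]) - thr) / (abs(vg_s[i0]) - abs(vg_s[i0 - 1]))
      t_on <- t_on - min(max(fr, 0), 1) * dt
    }
    t_off <- record$time[i1]
    if (i1 < n && abs(vg_s[i1]) > abs(vg_s[i1 + 1])) {
      fr <- (abs(vg_s[i1]) - thr) / (abs(vg_s[i1]) - abs(vg_s[i1 + 1]))
      t_off <- t_off + min(max(fr, 0), 1) * dt
    }
    measure_event(record, i0, i1, dt, t_on, t_off)
  })
  ev <- do.call(rbind, rows)
  ev <- ev[abs(ev$gaze_displacement_deg) >= min_amplitude, , drop = FALSE]
  rownames(ev) <- NULL
  if (!is.null(condition_windows) && nrow(ev)) {
    ev$condition <- NA_character_
    for (i in seq_len(nrow(condition_windows))) {
      sel <- ev$saccade_onset_s >= condition_windows$t0[i] &
        ev$saccade_onset_s <= condition_windows$t1[i]
      ev$condition[sel] <- as.character(condition_windows$condition[i])
    }
  }
  class(ev) <- c("gaze_shift_events", "data.frame")
  attr(ev, "rate_hz") <- rate
  ev
}

empty_events <- function() {
  ev <- data.frame(saccade_onset_s = numeric(0), saccade_offset_s = numeric(0),
                   saccade_duration_s = numeric(0),
                   gaze_displacement_deg = numeric(0),
                   gaze_amplitude_deg = numeric(0),
                   saccade_displacement_deg = numeric(0),
                   saccade_amplitude_deg = numeric(0),
                   head_during_saccade_deg = numeric(0),
                   head_amplitude_deg = numeric(0),
                   head_movement_duration_s = numeric(0),
                   peak_gaze_velocity_dps = numeric(0),
                   peak_eye_velocity_dps = numeric(0),
                   peak_head_velocity_dps = numeric(0),
                   vor_start_s = numeric(0), vor_end_s = numeric(0),
                   vor_gain = numeric(0),
                   pre_eye_vel_dps = numeric(0), pre_head_vel_dps = numeric(0),
                   post_eye_vel_dps = numeric(0), post_head_vel_dps = numeric(0),
                   head_lead = logical(0), context_ok = logical(0),
                   condition = character(0))
  class(ev) <- c("gaze_shift_events", "data.frame")
  ev
}

# measure one refined event [i0, i1] (sample indices of onset/offset);
# t_on/t_off carry the sub-sample interpolated boundary times
measure_event <- function(record, i0, i1, dt, t_on = NULL, t_off = NULL) {
  n <- nrow(record)
  if (is.null(t_on)) t_on <- record$time[i0]
  if (is.null(t_off)) t_off <- record$time[i1]
  vor <- vor_bounds(record, i1, dt)
  # head movement interval: walk back from onset while the head still moves
  h0 <- i0
  while (h0 > 1 && abs(record$dH_dps[h0 - 1]) >= 10) h0 <- h0 - 1
  h1 <- vor["i_end"]
  ppv <- pre_post_velocities_idx(record, i0, dt)
  seg <- h0:h1
  ev <- data.frame(
    saccade_onset_s = t_on, saccade_offset_s = t_off,
    saccade_duration_s = t_off - t_on,
    gaze_displacement_deg = record$G_deg[i1] - record$G_deg[i0],
    gaze_amplitude_deg = abs(record$G_deg[i1] - record$G_deg[i0]),
    saccade_displacement_deg = record$E_deg[i1] - record$E_deg[i0],
    saccade_amplitude_deg = abs(record$E_deg[i1] - record$E_deg[i0]),
    head_during_saccade_deg = record$H_deg[i1] - record$H_deg[i0],
    head_amplitude_deg = abs(record$H_deg[h1] - record$H_deg[h0]),
    head_movement_duration_s = record$time[h1] - record$time[h0],
    peak_gaze_velocity_dps = max(abs(sg_vel(record$G_deg, i0, i1, dt))),
    peak_eye_velocity_dps = max(abs(sg_vel(record$E_deg, i0, i1, dt))),
    peak_head_velocity_dps = max(abs(sg_vel(record$H_deg, seg[1], seg[length(seg)], dt))),
    vor_start_s = vor["t_start"], vor_end_s = vor["t_end"],
    vor_gain = vor["gain"],
    pre_eye_vel_dps = ppv["pre_eye"], pre_head_vel_dps = ppv["pre_head"],
    post_eye_vel_dps = ppv["post_eye"], post_head_vel_dps = ppv["post_head"],
    context_ok = ppv["ok"] > 0)
  ev$head_lead <- classify_head_lead(ev)
  ev$condition <- NA_character_
  ev
}

# smoothed velocity of channel x over [i0, i1] (uses neighbouring context)
sg_vel <- function(x, i0, i1, dt) {
  lo <- max(1, i0 - 3); hi <- min(length(x), i1 + 3)
  v <- estimate_velocity(x[lo:hi], dt, "sgolay")
  v[(i0 - lo + 1):(i1 - lo + 1)]
}

# VOR phase bounds and gain following a saccade offset at index i1.
# The detected offset (10% of peak gaze velocity) precedes the true saccade
# end, and VOR suppression wanes gradually rather than instantaneously, so
# the gain window skips a short settle period and any leading samples in
# which the eye does not yet counter-rotate against the head.
vor_bounds <- function(record, i1, dt, head_still = 10, settle_s = 0.02) {
  n <- nrow(record)
  if (i1 >= n || abs(record$dH_dps[min(i1 + 1, n)]) < head_still) {
    return(c(i_end = i1, t_start = NA_real_, t_end = NA_real_,
             gain = NA_real_))
  }
  j <- i1 + 1
  while (j < n && abs(record$dH_dps[j + 1]) >= head_still) j <- j + 1
  i_skip <- min(i1 + 1 + ceiling(settle_s / dt), j)
  gidx <- i_skip:j
  gain <- if (length(gidx) >= 2 && abs(mean(record$dH_dps[gidx])) > 1e-9) {
    -mean(record$dE_dps[gidx]) / mean(record$dH_dps[gidx])
  } else NA_real_
  c(i_end = j, t_start = record$time[i1], t_end = record$time[j],
    gain = gain)
}

#' VOR phase of one detected event
#'
#' The interval from the saccade offset until the head velocity |dH| falls
#' below `head_still` (head movement end); within it the eye-head velocity
#' gain g = -mean(dE)/mean(dH) quantifies how completely the
#' vestibulo-ocular reflex counter-rotates the eye. When the head is already
#' stationary at saccade offset the phase is empty and the gain NA.
#'
#' @param record A `gaze_record`.
#' @param event One row of the events table from [detect_gaze_saccades()].
#' @param head_still Head-stationary threshold, deg/s (default 10).
#' @return List `t_start`, `t_end`, `gain`; `t_start`/`t_end` are NA for an
#'   empty phase.
#' @export
vor_phase <- function(record, event, head_still = 10) {
  stopifnot(inherits(record, "gaze_record"))
  i1 <- which.min(abs(record$time - event$saccade_offset_s))
  b <- vor_bounds(record, i1, 1 / attr(record, "rate_hz"), head_still)
  list(t_start = unname(b["t_start"]), t_end = unname(b["t_end"]),
       gain = unname(b["gain"]))
}

# mean eye/head velocities in [onset - 100 ms, onset) and [onset, onset + 100 ms]
pre_post_velocities_idx <- function(record, i0, dt, window_s = 0.1) {
  w <- round(window_s / dt)
  n <- nrow(record)
  ok <- (i0 - w) >= 1 && (i0 + w) <= n
  if (!ok) {
    return(c(pre_eye = NA_real_, pre_head = NA_real_, post_eye = NA_real_,
             post_head = NA_real_, ok = 0))
  }
  pre <- (i0 - w):(i0 - 1)
  post <- i0:(i0 + w)
  c(pre_eye = mean(record$dE_dps[pre]), pre_head = mean(record$dH_dps[pre]),
    post_eye = mean(record$dE_dps[post]), post_head = mean(record$dH_dps[post]),
    ok = 1)
}

#' Pre- and post-onset eye and head velocities
#'
#' Mean eye-in-head and head velocities over the 100 ms preceding and the
#' 100 ms following the saccade onset. These windows drive the head-lead
#' classification; the wider -250 ms to +750 ms span around the onset is the
#' per-event analysis epoch used for plotting and peak extraction, not for
#' these averages.
#'
#' @param record A `gaze_record`.
#' @param event One row of the events table.
#' @param window_s Averaging window length (default 0.1 s).
#' @return Named numeric `pre_eye`, `pre_head`, `post_eye`, `post_head`
#'   (deg/s) plus `ok` (1 when enough context existed).
#' @export
pre_post_velocities <- function(record, event, window_s = 0.1) {
  stopifnot(inherits(record, "gaze_record"))
  i0 <- which.min(abs(record$time - event$saccade_onset_s))
  pre_post_velocities_idx(record, i0, 1 / attr(record, "rate_hz"), window_s)
}

#' Classify whether the head led the saccade
#'
#' TRUE when the head was already moving before the saccade started
#' (|pre-onset head velocity| > `moving_threshold`) in the same direction it
#' moves after the onset. Comparing velocities rather than head-movement
#' onsets is robust for participants who never fully stabilize the head.
#'
#' @param event Event row(s) with `pre_head_vel_dps` and `post_head_vel_dps`.
#' @param moving_threshold Head-moving threshold, deg/s (default 5).
#' @return Logical vector.
#' @export
classify_head_lead <- function(event, moving_threshold = 5) {
  abs(event$pre_head_vel_dps) > moving_threshold &
    sign(event$pre_head_vel_dps) == sign(event$post_head_vel_dps)
}

#' Per-condition eye-head coordination summary
#'
#' Means and standard errors of the mean, per condition, of saccade
#' amplitude, gaze amplitude, peak saccade (eye) velocity, saccade duration
#' and peak head velocity; the head-velocity slope (least-squares regression
#' through the origin of per-event peak head velocity on gaze amplitude, in
#' 1/s); the fraction of events in which the head led; and a sublinearity
#' flag indicating that the ratio of saccade to gaze amplitude decreases
#' across conditions (the saccade's relative contribution shrinks for larger
#' gaze shifts). Conditions are ordered by mean gaze amplitude; the
#' per-condition table reports both the condition label (nominal target
#' separation) and the measured mean gaze amplitude, since either can serve
#' as the abscissa of a main-sequence plot.
#'
#' @param events A `gaze_shift_events` table with condition labels.
#' @param min_events Minimum events per condition (default 3).
#' @return A `coordination_summary` list: `per_condition` data frame,
#'   `head_velocity_slope_per_s`, `head_velocity_slope_se`,
#'   `head_leads_fraction`, `saccade_sublinear`.
#' @export
coordination_summary <- function(events, min_events = 3) {
  ev <- events[!is.na(events$condition), , drop = FALSE]
  if (!nrow(ev)) stop("no events with condition labels")
  counts <- table(ev$condition)
  deficient <- names(counts)[counts < min_events]
  if (length(deficient)) {
    stop("too few events (< ", min_events, ") in condition(s): ",
         paste(deficient, collapse = ", "))
  }
  if (length(counts) < 2) stop("need at least 2 conditions")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  agg <- function(var) {
    m <- tapply(ev[[var]], ev$condition, mean)
    s <- tapply(ev[[var]], ev$condition, sem)
    list(mean = m, sem = s)
  }
  ga <- agg("gaze_amplitude_deg")
  sa <- agg("saccade_amplitude_deg")
  pv <- agg("peak_eye_velocity_dps")
  sd_ <- agg("saccade_duration_s")
  hv <- agg("peak_head_velocity_dps")
  ord <- order(ga$mean)
  per <- data.frame(
    condition = names(ga$mean)[ord],
    n = as.integer(counts[names(ga$mean)[ord]]),
    gaze_amplitude_deg = as.numeric(ga$mean[ord]),
    gaze_amplitude_sem = as.numeric(ga$sem[ord]),
    saccade_amplitude_deg = as.numeric(sa$mean[ord]),
    saccade_amplitude_sem = as.numeric(sa$sem[ord]),
    peak_saccade_velocity_dps = as.numeric(pv$mean[ord]),
    peak_saccade_velocity_sem = as.numeric(pv$sem[ord]),
    saccade_duration_s = as.numeric(sd_$mean[ord]),
    saccade_duration_sem = as.numeric(sd_$sem[ord]),
    peak_head_velocity_dps = as.numeric(hv$mean[ord]),
    peak_head_velocity_sem = as.numeric(hv$sem[ord]))
  # slope through the origin of per-event peak head velocity vs gaze amplitude
  a <- ev$gaze_amplitude_deg
  v <- ev$peak_head_velocity_dps
  slope <- sum(v * a) / sum(a^2)
  resid <- v - slope * a
  slope_se <- sqrt(sum(resid^2) / (length(a) - 1) / sum(a^2))
  ratio <- per$saccade_amplitude_deg / per$gaze_amplitude_deg
  sublinear <- all(diff(ratio) < 1e-6)
  hl <- ev$head_lead[ev$context_ok]
  structure(
    list(per_condition = per,
         head_velocity_slope_per_s = slope,
         head_velocity_slope_se = slope_se,
         head_leads_fraction = mean(hl),
         saccade_sublinear = sublinear,
         n_events = nrow(ev)),
    class = "coordination_summary")
}

#' @export
print.coordination_summary <- function(x, ...) {
  cat(sprintf("<coordination_summary> %d events, %d conditions\n",
              x$n_events, nrow(x$per_condition)))
  cat(sprintf("  head velocity slope: %.3f 1/s (se %.3f)\n",
              x$head_velocity_slope_per_s, x$head_velocity_slope_se))
  cat(sprintf("  head leads fraction: %.2f\n", x$head_leads_fraction))
  cat(sprintf("  saccade amplitude sublinear in gaze amplitude: %s\n",
              x$saccade_sublinear))
  print(x$per_condition, digits = 3)
  invisible(x)
}
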