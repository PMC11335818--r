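#' Timestamped sampled signal
#'
#' A possibly irregularly sampled scalar channel with validity flags; the
#' container for raw eye-in-head (E) and head (H) angle streams.
#'
#' @param timestamps Numeric, seconds, monotone increasing.
#' @param values Numeric, degrees.
#' @param valid Logical validity flags (default all valid).
#' @return An object of class `sampled_signal` (a list with `timestamps`,
#'   `values`, `valid`).
#' @export
sampled_signal <- function(timestamps, values, valid = NULL) {
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (is.null(valid)) valid <- rep(TRUE, length(timestamps))
  valid <- as.logical(valid) & is.finite(values) & is.finite(timestamps)
  stopifnot(length(values) == length(timestamps),
            length(valid) == length(timestamps))
  if (length(timestamps) > 1 && any(diff(timestamps) < 0)) {
    stop("timestamps must be monotone increasing")
  }
  if (any(!is.finite(values[valid]))) stop("valid samples must be finite")
  structure(list(timestamps = timestamps, values = values, valid = valid),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples (%d valid), %.3f-%.3f s\n",
              length(x$timestamps), sum(x$valid),
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Resample a signal to a uniform rate
#'
#' Linear interpolation of the valid samples onto a uniform grid with spacing
#' exactly `1/rate`. Grid points farther than `max_gap` from the nearest
#' valid input sample are marked invalid rather than extrapolated, so short
#' dropouts are bridged while long ones stay visible downstream. The
#' interpolant is exact for linear signals and leaves an already-uniform
#' signal unchanged when the grid matches its own timestamps.
#'
#' @param signal A [sampled_signal()].
#' @param rate Target rate in Hz (default 200).
#' @param range Optional length-2 numeric giving the grid span in seconds;
#'   defaults to the signal's own valid span. Supplying a common range is how
#'   two streams are brought onto one shared grid before fusion.
#' @param max_gap Maximum distance (s) to the nearest valid sample for a grid
#'   point to be valid; default 0.05 (50 ms).
#' @return A uniform [sampled_signal()].
#' @export
resample_to_rate <- function(signal, rate = 200, range = NULL,
                             max_gap = 0.05) {
  stopifnot(inherits(signal, "sampled_signal"), rate > 0)
  tv <- signal$timestamps[signal$valid]
  xv <- signal$values[signal$valid]
  if (length(tv) < 2) stop("need at least 2 valid samples to resample")
  if (is.null(range)) range <- c(tv[1], tv[length(tv)])
  dt <- 1 / rate
  n <- floor((range[2] - range[1]) / dt + 1e-9) + 1
  grid <- range[1] + (seq_len(n) - 1) * dt
  vals <- stats::approx(tv, xv, xout = grid, rule = 2)$y
  # distance from each grid point to the nearest valid input sample
  idx <- findInterval(grid, tv)
  d_lo <- ifelse(idx >= 1, grid - tv[pmax(idx, 1)], Inf)
  d_hi <- ifelse(idx < length(tv), tv[pmin(idx + 1, length(tv))] - grid, Inf)
  ok <- pmin(d_lo, d_hi) <= max_gap + 1e-12
  vals[!ok] <- NA_real_
  sampled_signal(grid, vals, ok)
}

# Savitzky-Golay quadratic smoother, window of 5 samples.
# Exact for locally quadratic signals, so it does not bias bell-shaped
# velocity profiles at the scale of the 5-ms sample interval.
sg5_smooth <- function(x) {
  n <- length(x)
  if (n < 5) return(x)
  w <- c(-3, 12, 17, 12, -3) / 35
  pad <- c(x[1], x[1], x, x[n], x[n])
  stats::filter(pad, w, sides = 2)[3:(n + 2)]
}

#' Velocity of a uniformly sampled series
#'
#' Central difference, optionally preceded by a 5-sample local-quadratic
#' (Savitzky-Golay) smoother. The smoothed variant is used for event
#' detection on noisy recordings; the plain central difference is the
#' default for the fused record's velocity channels.
#'
#' @param x Numeric values (degrees).
#' @param dt Sample interval in seconds.
#' @param method `"central"` or `"sgolay"`.
#' @return Velocities in degrees/second (same length; endpoints use one-sided
#'   differences).
#' @export
estimate_velocity <- function(x, dt, method = c("central", "sgolay")) {
  method <- match.arg(method)
  if (method == "sgolay") x <- sg5_smooth(x)
  n <- length(x)
  if (n < 2) return(rep(NA_real_, n))
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- (x[2] - x[1]) / dt
  v[n] <- (x[n] - x[n - 1]) / dt
  v
}

#' Recover the clock offset between the eye and head streams
#'
#' During the head-oscillation synchronization episodes the participant
#' fixates while shaking the head, so eye-in-head velocity mirrors head
#' velocity (dE = -dH). The offset is the lag maximizing the normalized
#' cross-correlation of dE with -dH, computed on uniformly resampled
#' velocity signals and refined to sub-sample precision by parabolic
#' interpolation of the correlation peak. Velocities rather than positions
#' are correlated so slow drifts and constant offsets cancel.
#'
#' A positive offset means the eye clock runs ahead of the head clock:
#' subtract it from the eye timestamps to align the streams.
#'
#' @param eye,head [sampled_signal()] angle streams (degrees).
#' @param search_window Maximum |offset| searched, seconds (default 1).
#' @param rate Internal resampling rate, Hz.
#' @param segments Optional data frame with columns `t0`, `t1` (seconds, head
#'   clock) restricting the correlation to known oscillation episodes; when
#'   `NULL` an energy detector locates 2-s windows in which the head
#'   oscillates with velocity amplitude above `min_amplitude`.
#' @param min_peak_correlation Error below this peak correlation (default
#'   0.5), since the oscillation signature is then absent.
#' @param min_amplitude Minimum head-velocity amplitude (deg/s) for the
#'   energy detector.
#' @return The offset in seconds, with attributes `peak_correlation` and
#'   `lag_grid_s`.
#' @export
synchronize <- function(eye, head, search_window = 1, rate = 200,
                        segments = NULL, min_peak_correlation = 0.5,
                        min_amplitude = 20) {
  stopifnot(inherits(eye, "sampled_signal"), inherits(head, "sampled_signal"),
            search_window > 0)
  dt <- 1 / rate
  # common grid covering both streams (eye may be shifted by up to the window)
  t0 <- min(head$timestamps[1], eye$timestamps[1])
  t1 <- max(head$timestamps[length(head$timestamps)],
            eye$timestamps[length(eye$timestamps)])
  eu <- resample_to_rate(eye, rate, range = c(t0, t1))
  hu <- resample_to_rate(head, rate, range = c(t0, t1))
  ve <- estimate_velocity(eu$values, dt, "sgolay")
  vh <- estimate_velocity(hu$values, dt, "sgolay")
  ve[!eu$valid] <- NA_real_
  vh[!hu$valid] <- NA_real_

  keep <- rep(FALSE, length(vh))
  if (!is.null(segments)) {
    for (i in seq_len(nrow(segments))) {
      keep <- keep | (hu$timestamps >= segments$t0[i] &
                      hu$timestamps <= segments$t1[i])
    }
  } else {
    keep <- detect_oscillation_mask(vh, rate, min_amplitude)
    if (!any(keep, na.rm = TRUE)) {
      stop("no oscillation signature found: the head-velocity energy ",
           "detector located no oscillation episode")
    }
  }
  max_lag <- ceiling(search_window / dt)
  r <- xcorr_lags(ve, -vh, keep, max_lag)
  if (all(!is.finite(r))) stop("no overlapping valid samples for synchronization")
  ipk <- which.max(r)
  if (r[ipk] < min_peak_correlation) {
    stop(sprintf(paste0("no oscillation signature found: peak eye/head ",
                        "velocity correlation %.2f is below %.2f"),
                 r[ipk], min_peak_correlation))
  }
  lag <- ipk - (max_lag + 1)
  # parabolic sub-sample refinement around the peak
  frac <- 0
  if (ipk > 1 && ipk < length(r) && is.finite(r[ipk - 1]) && is.finite(r[ipk + 1])) {
    den <- r[ipk - 1] - 2 * r[ipk] + r[ipk + 1]
    if (den < 0) frac <- 0.5 * (r[ipk - 1] - r[ipk + 1]) / den
  }
  offset <- (lag + frac) * dt
  attr(offset, "peak_correlation") <- r[ipk]
  attr(offset, "lag_grid_s") <- dt
  offset
}

# normalized cross-correlation of a with b at integer lags -max_lag..max_lag,
# restricted to positions where keep[i + lag] is TRUE (b-aligned mask).
# positive lag means a runs ahead of b by lag samples.
xcorr_lags <- function(a, b, keep, max_lag) {
  n <- length(a)
  r <- rep(NA_real_, 2 * max_lag + 1)
  for (k in -max_lag:max_lag) {
    ia <- max(1, 1 + k):min(n, n + k)  # indices into a
    ib <- ia - k                       # aligned indices into b
    sel <- keep[ib] & is.finite(a[ia]) & is.finite(b[ib])
    if (sum(sel) < 20) next
    x <- a[ia][sel]; y <- b[ib][sel]
    x <- x - mean(x); y <- y - mean(y)
    d <- sqrt(sum(x^2) * sum(y^2))
    if (d > 0) r[k + max_lag + 1] <- sum(x * y) / d
  }
  r
}

# sliding 2-s-window energy detector for head oscillation episodes: windows
# whose head-velocity RMS amplitude exceeds min_amplitude/sqrt(2) and which
# contain at least 2 full cycles worth of zero crossings.
detect_oscillation_mask <- function(vh, rate, min_amplitude = 20) {
  n <- length(vh)
  w <- round(2 * rate)
  if (n < w) return(rep(FALSE, n))
  v <- ifelse(is.finite(vh), vh, 0)
  cs2 <- cumsum(c(0, v^2))
  zc <- cumsum(c(0, 0, abs(diff(sign(v))) > 0))
  keep <- rep(FALSE, n)
  starts <- seq(1, n - w + 1, by = max(1, round(w / 4)))
  for (s in starts) {
    e <- s + w - 1
    rms <- sqrt((cs2[e + 1] - cs2[s]) / w)
    ncross <- zc[e + 1] - zc[s]
    if (rms > min_amplitude / sqrt(2) && ncross >= 4) keep[s:e] <- TRUE
  }
  keep
}
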