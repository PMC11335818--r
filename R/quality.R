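#' Gaze accuracy over fixation windows
#'
#' Mean over fixation windows of the absolute difference between the median
#' calibrated gaze and the known target azimuth.
#'
#' @param record A `gaze_record` from [fuse()].
#' @param fixation_windows Data frame with columns `t0`, `t1` (seconds).
#' @param target_azimuths Target azimuths in degrees, one per window.
#' @param central_fraction Central window fraction used for the median.
#' @return Mean absolute accuracy in degrees, with per-window errors in the
#'   `per_window_deg` attribute.
#' @export
accuracy <- function(record, fixation_windows, target_azimuths,
                     central_fraction = 0.5) {
  stopifnot(inherits(record, "gaze_record"),
            nrow(fixation_windows) == length(target_azimuths))
  sig <- sampled_signal(record$time, record$G_deg, record$valid)
  med <- fixation_medians(sig, fixation_windows, central_fraction)
  err <- med - target_azimuths
  if (all(!is.finite(err))) stop("no valid fixation windows for accuracy")
  out <- mean(abs(err), na.rm = TRUE)
  attr(out, "per_window_deg") <- err
  out
}

#' RMS sample-to-sample precision (windowed median)
#'
#' The root-mean-square of successive sample differences is computed inside
#' every window of `window_samples` samples (the window slides by one
#' sample), and the median across windows is returned. Windows containing
#' invalid samples are skipped. Because saccades occupy a minority of
#' windows, the median is robust to them, so no fixation classification is
#' needed; the default window of 41 samples corresponds to 205 ms at 200 Hz
#' (n x dt bookkeeping).
#'
#' @param signal A [sampled_signal()]; expected (approximately) uniformly
#'   sampled. The statistic itself uses sample ordering only.
#' @param window_samples Samples per window (default 41, must be >= 2).
#' @return Median windowed RMS-S2S deviation in the units of the signal.
#' @export
rms_s2s_precision <- function(signal, window_samples = 41) {
  stopifnot(inherits(signal, "sampled_signal"), window_samples >= 2)
  x <- signal$values
  n <- length(x)
  if (n < window_samples) {
    stop("signal shorter than one window (", window_samples, " samples)")
  }
  d2 <- diff(x)^2
  d2[!(signal$valid[-n] & signal$valid[-1])] <- NA_real_
  m <- window_samples - 1          # differences per window
  cs <- cumsum(c(0, ifelse(is.finite(d2), d2, 0)))
  bad <- cumsum(c(0, !is.finite(d2)))
  starts <- seq_len(n - window_samples + 1)
  sums <- cs[starts + m] - cs[starts]
  nbad <- bad[starts + m] - bad[starts]
  rms <- sqrt(sums / m)
  rms[nbad > 0] <- NA_real_
  if (all(!is.finite(rms))) stop("every window contains invalid samples")
  stats::median(rms, na.rm = TRUE)
}

#' Effective sampling frequency
#'
#' Number of valid samples divided by the recording time span (first to last
#' timestamp); a data-loss-robust summary for trackers that never flag
#' invalid samples explicitly.
#'
#' @param timestamps Numeric, seconds.
#' @param valid Logical flags; defaults to all valid.
#' @return Effective frequency in Hz.
#' @export
effective_frequency <- function(timestamps, valid = NULL) {
  stopifnot(length(timestamps) >= 2)
  if (is.null(valid)) valid <- rep(TRUE, length(timestamps))
  span <- timestamps[length(timestamps)] - timestamps[1]
  if (span <= 0) stop("zero-duration recording")
  sum(valid) / span
}

#' Sample-interval distribution (modes of successive differences)
#'
#' Clusters the successive timestamp differences by one-dimensional two-means
#' (k = 2), reporting each cluster's mean and standard deviation in
#' milliseconds. When the two cluster centers are not separated beyond the
#' pooled within-cluster spread the distribution is treated as unimodal and a
#' single mode is reported. The eye tracker's interval distribution is
#' bimodal around 4 and 8 ms (an 8-ms interval is a skipped frame).
#'
#' @param timestamps Numeric, seconds (>= 10 samples).
#' @return Data frame `mode_ms, sd_ms, weight`, one row per mode, sorted by
#'   mode.
#' @export
interval_distribution <- function(timestamps) {
  stopifnot(length(timestamps) >= 10)
  d <- diff(timestamps) * 1000
  cl <- two_means_1d(d)
  sep <- abs(diff(cl$centers))
  pooled <- sum(cl$sd * cl$weight)
  if (length(cl$centers) < 2 || !is.finite(sep) ||
      sep < max(4 * pooled, 1e-3)) {
    return(data.frame(mode_ms = mean(d), sd_ms = stats::sd(d), weight = 1))
  }
  ord <- order(cl$centers)
  data.frame(mode_ms = cl$centers[ord], sd_ms = cl$sd[ord],
             weight = cl$weight[ord])
}

# Lloyd's algorithm in 1-D with k = 2, initialized at the extremes
two_means_1d <- function(x, max_iter = 100) {
  c1 <- min(x); c2 <- max(x)
  if (c2 - c1 < 1e-12) {
    return(list(centers = mean(x), sd = 0, weight = 1))
  }
  for (i in seq_len(max_iter)) {
    a <- abs(x - c1) <= abs(x - c2)
    n1 <- mean(x[a]); n2 <- mean(x[!a])
    if (isTRUE(all.equal(c(c1, c2), c(n1, n2), tolerance = 1e-12))) break
    c1 <- n1; c2 <- n2
  }
  sd1 <- if (sum(a) > 1) stats::sd(x[a]) else 0
  sd2 <- if (sum(!a) > 1) stats::sd(x[!a]) else 0
  list(centers = c(c1, c2), sd = c(sd1, sd2),
       weight = c(mean(a), mean(!a)))
}

#' Data-quality report for a processed recording
#'
#' Bundles the quality metrics: accuracy against the calibration targets,
#' windowed RMS-S2S precision of the raw eye-in-head, raw head, and fused
#' gaze signals, effective frequency of the raw eye stream, and its
#' sample-interval modes. Precision of E and H is computed on the raw
#' (pre-resampling) streams so that interpolation does not attenuate the
#' sample-to-sample noise.
#'
#' @param record Calibrated `gaze_record`.
#' @param E_raw,H_raw Raw [sampled_signal()]s (degrees).
#' @param fixation_windows,target_azimuths Calibration fixations, as in
#'   [accuracy()].
#' @param window_samples RMS-S2S window length in samples.
#' @return A `quality_report` list.
#' @export
quality_report <- function(record, E_raw, H_raw, fixation_windows,
                           target_azimuths, window_samples = 41) {
  acc <- accuracy(record, fixation_windows, target_azimuths)
  g_sig <- sampled_signal(record$time, record$G_deg, record$valid)
  structure(
    list(
      mean_absolute_accuracy_deg = as.numeric(acc),
      precision_rms_s2s_deg = c(
        E = rms_s2s_precision(E_raw, window_samples),
        H = rms_s2s_precision(H_raw, window_samples),
        G = rms_s2s_precision(g_sig, window_samples)),
      effective_frequency_hz = effective_frequency(E_raw$timestamps,
                                                   E_raw$valid),
      interval_modes = interval_distribution(E_raw$timestamps)),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  accuracy (mean abs): %.3f deg\n", x$mean_absolute_accuracy_deg))
  p <- x$precision_rms_s2s_deg
  cat(sprintf("  precision RMS-S2S:   E %.4f  H %.4f  G %.4f deg\n",
              p[["E"]], p[["H"]], p[["G"]]))
  cat(sprintf("  effective frequency: %.2f Hz\n", x$effective_frequency_hz))
  for (i in seq_len(nrow(x$interval_modes))) {
    cat(sprintf("  interval mode %d: %.2f ms (sd %.3f ms, weight %.2f)\n", i,
                x$interval_modes$mode_ms[i], x$interval_modes$sd_ms[i],
                x$interval_modes$weight[i]))
  }
  invisible(x)
}
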