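#' Zero-phase bandpass filter a raw recording
#'
#' Applies a forward-backward (zero-phase) 4th-order Butterworth bandpass,
#' the standard pre-filter for extracellular spike detection (default band
#' 300-3000 Hz). Zero-phase filtering preserves spike shapes and trough
#' positions.
#'
#' @param raw A `raw_recording`.
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @param order Butterworth order (per pass).
#' @return A `filtered_recording` with fields `samples`, `band`,
#'   `sampling_rate`, same length as the input.
#' @export
bandpass_filter <- function(raw, low = 300, high = 3000, order = 4L) {
  fs <- raw$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("band edges must satisfy 0 < low < high < sampling_rate/2.")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, raw$samples)
  structure(
    list(samples = as.numeric(y), band = c(low, high), sampling_rate = fs,
         channel_id = raw$channel_id),
    class = "filtered_recording"
  )
}

#' Robust background-noise estimate
#'
#' Estimates the noise standard deviation of a filtered extracellular signal
#' as `median(|x|) / 0.6745`. The denominator is the median of the absolute
#' value of a standard normal, so under Gaussian noise the estimate converges
#' to the true sd while being insensitive to the sparse spike fraction.
#'
#' @param filtered A `filtered_recording`, or a numeric vector.
#' @return The noise scale sigma_m in the signal's units (microvolts).
#' @examples
#' estimate_noise(c(0.5, 0.6745, 10))  # 1
#' @export
estimate_noise <- function(filtered) {
  x <- if (is.list(filtered)) filtered$samples else filtered
  if (length(x) == 0L) abort("empty signal.")
  median(abs(x)) / 0.6745
}

#' Threshold detection of negative-going spikes
#'
#' Flags samples where the signal first crosses below `-multiplier * sigma_m`
#' (negative-deflection convention, matching trough-based alignment).
#' Crossings within `dead_time` of an accepted event are suppressed, and
#' events too close to either edge of the recording for a full extraction
#' window are dropped.
#'
#' @param filtered A `filtered_recording`.
#' @param sigma_m Noise scale from [estimate_noise()].
#' @param multiplier Threshold multiplier (default 5).
#' @param dead_time Suppression window after each event, seconds (default
#'   3.2 ms, one extraction window, so filter ringing and rebound
#'   undershoot of a large spike cannot re-trigger detection).
#' @param edge_margin Samples to keep clear of each recording edge
#'   (default 96, enough for a provisional plus re-aligned 64-sample window).
#' @return A tibble of spike events: `threshold_index`, `channel_id`.
#' @export
detect_spikes <- function(filtered, sigma_m, multiplier = 5,
                          dead_time = 0.0032, edge_margin = 96L) {
  if (multiplier < 0) abort("`multiplier` must be >= 0.")
  if (sigma_m < 0) abort("`sigma_m` must be >= 0.")
  x <- filtered$samples
  thr <- -multiplier * sigma_m
  below <- x < thr
  # first samples of below-threshold runs
  cross <- which(below & !c(FALSE, below[-length(below)]))
  dead <- as.integer(round(dead_time * filtered$sampling_rate))
  keep <- logical(length(cross))
  last <- -Inf
  for (i in seq_along(cross)) {
    if (cross[i] - last > dead) {
      keep[i] <- TRUE
      last <- cross[i]
    }
  }
  idx <- cross[keep]
  idx <- idx[idx > edge_margin & idx <= length(x) - edge_margin]
  tibble::tibble(threshold_index = idx,
                 channel_id = filtered$channel_id %||% NA_character_)
}

#' Extract trough-aligned 64-sample spike waveforms
#'
#' For each detected event, cuts a provisional window of `pre_points` samples
#' before and `post_points` after the threshold crossing (64 samples total by
#' default), locates its minimum, then re-cuts 20 samples before and 43 after
#' the trough so that every emitted waveform has length 64 with its minimum
#' at a fixed position (offset 20 from the window start, i.e. the 21st
#' sample). Events whose re-cut window would overflow the recording are
#' discarded and counted in the `n_discarded` attribute.
#'
#' @param filtered A `filtered_recording`.
#' @param events Tibble from [detect_spikes()] (or integer vector of
#'   threshold indices).
#' @param pre_points,post_points Provisional window split around the
#'   threshold crossing; must sum to 64.
#' @return A `spike_waveforms` object: list with `waveforms` (n x 64 matrix,
#'   microvolts), `trough_index` (absolute sample index per spike),
#'   `threshold_index`, `trough_offset` (always 20) and attribute
#'   `n_discarded`.
#' @export
extract_waveforms <- function(filtered, events, pre_points = 20L,
                              post_points = 44L) {
  if (pre_points + post_points != 64L) {
    abort("`pre_points` + `post_points` must equal 64.")
  }
  idx <- if (is.data.frame(events)) events$threshold_index else as.integer(events)
  x <- filtered$samples
  n <- length(x)
  wf <- matrix(NA_real_, nrow = length(idx), ncol = 64L)
  trough_abs <- integer(length(idx))
  ok <- logical(length(idx))
  for (i in seq_along(idx)) {
    e <- idx[i]
    lo <- e - pre_points
    hi <- e + post_points - 1L
    if (lo < 1L || hi > n) next
    win <- x[lo:hi]
    tr <- lo + which.min(win) - 1L   # absolute trough index
    # iterate alignment to a fixed point: the re-cut window may expose a
    # deeper minimum (e.g. an overlapping larger spike); the trough value
    # strictly decreases each move, so this converges
    bad <- FALSE
    for (pass in 1:8) {
      lo2 <- tr - 20L
      hi2 <- tr + 43L
      if (lo2 < 1L || hi2 > n) {
        bad <- TRUE
        break
      }
      m <- lo2 + which.min(x[lo2:hi2]) - 1L
      if (m == tr) break
      tr <- m
    }
    if (bad) next
    wf[i, ] <- x[lo2:hi2]
    trough_abs[i] <- tr
    ok[i] <- TRUE
  }
  # distinct threshold crossings that re-align to (nearly) the same trough
  # (e.g. a filter ringing lobe preceding a large spike) are one physical
  # event: keep the first
  keep_idx <- which(ok)
  if (length(keep_idx) > 1L) {
    dup <- c(FALSE, diff(trough_abs[keep_idx]) <= 2L)
    keep_idx <- keep_idx[!dup]
  }
  out <- list(waveforms = wf[keep_idx, , drop = FALSE],
              trough_index = trough_abs[keep_idx],
              threshold_index = idx[keep_idx],
              trough_offset = 20L)
  attr(out, "n_discarded") <- length(idx) - length(keep_idx)
  class(out) <- "spike_waveforms"
  out
}

#' Normalized-gradient preprocessing of spike waveforms
#'
#' Each 64-sample waveform is min-max scaled to [0, 1] and then mapped to its
#' first-difference gradient, `(x[t+1] - x[t]) / dt` with `dt` the sampling
#' step (50 microseconds at 20 kHz), yielding a 63-value feature vector in
#' 1/seconds. The min-max step removes per-spike offset and gain, so the
#' features are invariant to affine rescaling of the waveform; the gradient
#' emphasises shape over amplitude and is the representation fed to the
#' clustering models. Constant (flat) waveforms have no min-max scale and are
#' rejected, with the count reported in the `n_rejected` attribute.
#'
#' @param waveforms A `spike_waveforms` object or an n x 64 numeric matrix.
#' @param sampling_rate Sampling rate in Hz.
#' @return An n x 63 feature matrix (attribute `n_rejected` gives dropped
#'   constant waveforms; attribute `kept` the logical keep mask).
#' @export
preprocess_spikes <- function(waveforms, sampling_rate = 20000) {
  wf <- if (is.matrix(waveforms)) waveforms else waveforms$waveforms
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  rng_min <- apply(wf, 1L, min)
  rng_max <- apply(wf, 1L, max)
  keep <- (rng_max - rng_min) > 0
  scaled <- (wf[keep, , drop = FALSE] - rng_min[keep]) /
    (rng_max[keep] - rng_min[keep])
  d <- ncol(wf)
  grad <- (scaled[, 2:d, drop = FALSE] - scaled[, 1:(d - 1), drop = FALSE]) *
    sampling_rate
  attr(grad, "n_rejected") <- sum(!keep)
  attr(grad, "kept") <- keep
  grad
}

#' Run the full detection chain on a raw recording
#'
#' Convenience wrapper: bandpass filter, noise estimation, 5-sigma threshold
#' detection, trough alignment and gradient preprocessing in one call.
#'
#' @param raw A `raw_recording`.
#' @param low,high Filter band (Hz).
#' @param multiplier Threshold multiplier.
#' @param dead_time Detection dead time, seconds.
#' @return List with `filtered`, `sigma_m`, `events`, `waveforms`,
#'   `features` (n x 63 matrix) and `trough_index` aligned with the feature
#'   rows.
#' @export
detect_pipeline <- function(raw, low = 300, high = 3000, multiplier = 5,
                            dead_time = 0.0032) {
  filt <- bandpass_filter(raw, low, high)
  sig <- estimate_noise(filt)
  ev <- detect_spikes(filt, sig, multiplier, dead_time)
  wf <- extract_waveforms(filt, ev)
  feats <- preprocess_spikes(wf, raw$sampling_rate)
  kept <- attr(feats, "kept")
  list(filtered = filt, sigma_m = sig, events = ev, waveforms = wf,
       features = feats, trough_index = wf$trough_index[kept])
}
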