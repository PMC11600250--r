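#' Construct a calcium trace
#'
#' @param intensities Per-frame ROI mean fluorescence intensities
#'   (arbitrary units), finite.
#' @param frame_interval Seconds per frame (> 0); default 12.5 ms (10 ms
#'   exposure plus readout at 3x3 binning, 20,000 frames spanning ~250 s).
#' @param roi_id ROI label.
#' @return A `calcium_trace`.
#' @export
calcium_trace <- function(intensities, frame_interval = 0.0125,
                          roi_id = NA_character_) {
  stop_if_not_scalar_number(frame_interval, "frame_interval",
                            positive = TRUE)
  if (!all(is.finite(intensities))) abort("`intensities` must be finite.")
  structure(
    list(intensities = as.numeric(intensities),
         frame_interval = frame_interval, roi_id = roi_id),
    class = "calcium_trace"
  )
}

#' Photobleaching correction by polynomial subtraction
#'
#' Fits a least-squares polynomial of the given order to the full trace and
#' subtracts it, normalising traces to a common zero baseline. The fit uses
#' an orthogonal-polynomial basis on a rescaled time axis, so order-10 fits
#' of 20,000-frame traces stay well conditioned. The reconstruction
#' identity `residuals + fitted_baseline == intensities` holds exactly by
#' construction.
#'
#' @param trace A [calcium_trace()].
#' @param order Polynomial degree (default 10).
#' @return A `corrected_trace`: `residuals`, `fitted_baseline`, `order`,
#'   plus the frame interval and ROI id of the source trace.
#' @export
bleach_correct <- function(trace, order = 10L) {
  y <- trace$intensities
  n <- length(y)
  if (n <= order + 1L) {
    abort(sprintf("trace length (%d) must exceed order + 1 (%d).",
                  n, order + 1L))
  }
  tt <- seq(-1, 1, length.out = n)  # rescaled domain for conditioning
  if (stats::var(y) == 0) {
    baseline <- rep(y[1L], n)
  } else {
    fit <- lm(y ~ poly(tt, degree = order, raw = FALSE))
    baseline <- unname(stats::fitted(fit))
  }
  structure(
    list(residuals = y - baseline, fitted_baseline = baseline,
         order = as.integer(order), frame_interval = trace$frame_interval,
         roi_id = trace$roi_id),
    class = "corrected_trace"
  )
}

# Exact prominence of a local maximum at index p: height above the higher
# of the two key saddles (lowest point between the peak and the nearest
# strictly higher sample on each side, or the edge).
peak_prominence <- function(x, p) {
  n <- length(x)
  left_hi <- if (p > 1L) {
    higher <- which(x[seq_len(p - 1L)] > x[p])
    if (length(higher)) max(higher) else 0L
  } else 0L
  right_hi <- if (p < n) {
    higher <- which(x[(p + 1L):n] > x[p])
    if (length(higher)) p + min(higher) else n + 1L
  } else n + 1L
  left_base <- min(x[max(left_hi + 1L, 1L):p])
  right_base <- min(x[p:min(right_hi - 1L, n)])
  x[p] - max(left_base, right_base)
}

#' Detect calcium spikes as prominent local maxima
#'
#' Finds local maxima of the bleach-corrected residual trace that rise at
#' least `prominence_mult` times a robust noise scale (the median absolute
#' deviation of the residuals, scaled to the Gaussian sd) above the
#' corrected zero baseline, and whose topographic prominence also clears
#' that threshold (so shoulders of larger transients are not double
#' counted). Spike times are `(frame - 1) * frame_interval`; amplitudes are
#' the residual value at the peak, i.e. the fluorescence excursion above
#' the corrected common baseline.
#'
#' @param corrected A `corrected_trace` from [bleach_correct()].
#' @param prominence_mult Prominence/amplitude threshold in units of the
#'   noise scale (> 0, default 4).
#' @param min_gap_s Minimum separation between detected peaks in seconds
#'   (default 0.5); of two closer peaks, only the larger is kept. Guards
#'   against noise crests on the slow decay tail of one transient being
#'   counted twice.
#' @return A `calcium_spikes` tibble: `frame` and `time_s` (apex of the
#'   transient, the local maximum), `onset_frame` and `onset_time_s` (the
#'   left half-amplitude crossing, the standard rise-time estimate of the
#'   underlying event time) and `amplitude` (residual at the apex).
#' @export
detect_calcium_spikes <- function(corrected, prominence_mult = 4,
                                  min_gap_s = 0.5) {
  if (prominence_mult <= 0) abort("`prominence_mult` must be > 0.")
  r <- corrected$residuals
  n <- length(r)
  scale <- stats::mad(r)
  thr <- prominence_mult * scale
  empty <- tibble::tibble(frame = integer(0), time_s = numeric(0),
                          onset_frame = integer(0),
                          onset_time_s = numeric(0),
                          amplitude = numeric(0))
  class(empty) <- c("calcium_spikes", class(empty))
  if (n < 3L) return(empty)
  is_max <- c(FALSE, r[2:(n - 1)] > r[1:(n - 2)] &
                r[2:(n - 1)] >= r[3:n], FALSE)
  cand <- which(is_max)
  if (scale > 0) {
    cand <- cand[r[cand] >= thr]  # amplitude gate above the zero baseline
    cand <- cand[vapply(cand, function(p) peak_prominence(r, p) >= thr,
                        logical(1L))]
  }
  # suppress lesser peaks within min_gap of a larger one
  if (length(cand) > 1L && min_gap_s > 0) {
    gap <- min_gap_s / corrected$frame_interval
    ord <- cand[order(r[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= gap)) kept <- c(kept, p)
    }
    cand <- sort(kept)
  }
  if (!length(cand)) return(empty)
  onset <- vapply(cand, function(p) {
    half <- r[p] / 2
    j <- p
    # walk left along the rising edge, tolerating single-frame noise dips
    while (j > 1L && (r[j - 1L] >= half ||
                      (j > 2L && r[j - 2L] >= half))) {
      j <- j - 1L
    }
    j
  }, integer(1L))
  out <- tibble::tibble(
    frame = cand,
    time_s = (cand - 1L) * corrected$frame_interval,
    onset_frame = onset,
    onset_time_s = (onset - 1L) * corrected$frame_interval,
    amplitude = r[cand]
  )
  class(out) <- c("calcium_spikes", class(out))
  out
}

#' Fluorescence change over baseline (delta-F/F)
#'
#' Computes `(F - F0) / F0` per frame, with the basal fluorescence `F0` a
#' robust statistic of the raw trace (default: its 10th percentile).
#'
#' @param trace A [calcium_trace()].
#' @param baseline Either a positive number used directly as `F0`, or a
#'   function of the intensity vector returning `F0` (default the 10th
#'   percentile).
#' @return A tibble `time_s`, `dff`; attribute `F0` holds the baseline.
#' @export
delta_f_over_f <- function(trace,
                           baseline = function(x) quantile(x, 0.10)) {
  f <- trace$intensities
  f0 <- if (is.function(baseline)) unname(baseline(f)) else baseline
  if (!is.finite(f0) || f0 <= 0) {
    abort("baseline fluorescence F0 must be positive.")
  }
  out <- tibble::tibble(
    time_s = (seq_along(f) - 1L) * trace$frame_interval,
    dff = (f - f0) / f0
  )
  attr(out, "F0") <- f0
  out
}

#' Align calcium spikes with an electrophysiology spike train
#'
#' Shifts calcium spike times back by the recorded start-time offset
#' between the two acquisitions and counts co-occurrences: calcium spikes
#' with at least one electrophysiological spike within the tolerance window
#' (default +-1 s, covering the sub-second unaccounted delay of the manual
#' alignment procedure).
#'
#' @param ephys_spikes A [spike_train()] or numeric vector of spike times
#'   in seconds.
#' @param calcium_spikes A `calcium_spikes` tibble from
#'   [detect_calcium_spikes()].
#' @param offset Start-time difference in seconds (calcium clock minus
#'   ephys clock); calcium times are shifted by `-offset`.
#' @param tolerance Co-occurrence window in seconds (default 1).
#' @return A list: `events` (tibble `time_s`, `aligned_time_s`,
#'   `nearest_ephys_s`, `delta_s`, `co_occurring`), `n_co_occurring`,
#'   `fraction_co_occurring`.
#' @export
align_traces <- function(ephys_spikes, calcium_spikes, offset = 0,
                         tolerance = 1) {
  if (!is.finite(offset)) abort("`offset` must be finite.")
  et <- if (is.list(ephys_spikes)) ephys_spikes$times else
    sort(as.numeric(ephys_spikes))
  ct <- calcium_spikes$time_s
  aligned <- ct - offset
  if (length(et) == 0L) {
    nearest <- rep(NA_real_, length(aligned))
    delta <- rep(Inf, length(aligned))
  } else {
    pos <- findInterval(aligned, et)
    lo <- pmax(pos, 1L)
    hi <- pmin(pos + 1L, length(et))
    d_lo <- abs(aligned - et[lo])
    d_hi <- abs(aligned - et[hi])
    nearest <- ifelse(d_lo <= d_hi, et[lo], et[hi])
    delta <- pmin(d_lo, d_hi)
  }
  co <- is.finite(delta) & delta <= tolerance
  list(
    events = tibble::tibble(time_s = ct, aligned_time_s = aligned,
                            nearest_ephys_s = nearest, delta_s = delta,
                            co_occurring = co),
    n_co_occurring = sum(co),
    fraction_co_occurring = if (length(co)) mean(co) else NA_real_
  )
}

#' Per-day population activity relative to day 1
#'
#' Summarises a cohort of spike event tables (electrophysiological or
#' calcium) by treatment group and recording day: mean spike rate across
#' units and mean pairwise mutual-information synchronicity, each divided
#' by the group's day-1 value, with the standard error of the mean per
#' cell (0 for a single unit or pair).
#'
#' @param events Tibble with columns `group`, `day`, `id` (unit/ROI label)
#'   and `time_s` (event times in seconds). Units with no events must still
#'   appear (with NA `time_s`) to be counted.
#' @param duration Recording duration per unit, seconds.
#' @param bin_width Mutual-information bin width, seconds (default 20 ms
#'   for electrophysiology; use one frame interval for calcium).
#' @return Tibble `group`, `day`, `metric` ("rate" or "synchronicity"),
#'   `value`, `relative` (value / day-1 value), `sem_relative`.
#' @export
population_summary <- function(events, duration, bin_width = 0.02) {
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  needed <- c("group", "day", "id", "time_s")
  if (!all(needed %in% names(events))) {
    abort("`events` needs columns group, day, id, time_s.")
  }
  cells <- list()
  for (g in unique(events$group)) {
    eg <- events[events$group == g, ]
    days <- sort(unique(eg$day))
    if (!1 %in% days) abort(sprintf("group '%s' has no day-1 reference.", g))
    for (d in days) {
      ed <- eg[eg$day == d, ]
      ids <- unique(ed$id)
      trains <- lapply(ids, function(u) {
        tm <- ed$time_s[ed$id == u]
        spike_train(tm[is.finite(tm)], duration, source = u)
      })
      rates <- vapply(trains, spike_rate, numeric(1L))
      mis <- if (length(trains) >= 2L) {
        prs <- utils::combn(length(trains), 2L)
        apply(prs, 2L, function(p) {
          mutual_information(trains[[p[1L]]], trains[[p[2L]]], bin_width)
        })
      } else {
        NA_real_
      }
      cells[[length(cells) + 1L]] <- tibble::tibble(
        group = g, day = d,
        metric = c("rate", "synchronicity"),
        value = c(mean(rates), mean(mis)),
        sem = c(
          if (length(rates) > 1L) sd(rates) / sqrt(length(rates)) else 0,
          if (length(mis) > 1L && all(is.finite(mis))) {
            sd(mis) / sqrt(length(mis))
          } else 0
        )
      )
    }
  }
  tab <- dplyr::bind_rows(cells)
  ref <- tab[tab$day == 1, c("group", "metric", "value")]
  names(ref)[3L] <- "day1_value"
  tab <- dplyr::left_join(tab, ref, by = c("group", "metric"))
  tab$relative <- tab$value / tab$day1_value
  tab$sem_relative <- tab$sem / tab$day1_value
  tab$day1_value <- NULL
  tab$sem <- NULL
  tab
}
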