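#' Biphasic extracellular spike templates
#'
#' Generates a bank of single-unit spike templates, one per source neuron.
#' Each template is a difference of two Gaussian lobes: a dominant negative
#' trough (the extracellular signature of the somatic action potential near
#' an electrode) followed by a smaller positive rebound. The trough sits at
#' 35% of the template length; lobe widths, rebound amplitude and rebound
#' latency are drawn at random per neuron so that distinct neurons have
#' distinct shapes, and the trough amplitude is drawn uniformly from
#' `amplitude_range`.
#'
#' @param n_neurons Number of source neurons (>= 1).
#' @param template_length Samples per template (>= 64).
#' @param amplitude_range Length-2 numeric giving the interval (in microvolts,
#'   negative trough convention) from which trough amplitudes are drawn.
#' @param rng_seed Integer seed; the same seed reproduces the same bank.
#' @param min_separation Minimum pairwise distance between templates in the
#'   representation the sorters actually see: the min-max-normalised
#'   gradient of the bandpass-filtered (300-3000 Hz) waveform, in
#'   per-sample RMS units. Candidate templates closer than this to an
#'   already accepted one are redrawn (with whole-bank restarts), so
#'   distinct source neurons are guaranteed distinguishable in feature
#'   space.
#' @param sampling_rate Sampling rate (Hz) assumed when filtering candidate
#'   templates for the separation check.
#' @return A list of `spike_template` objects, each with fields `neuron_id`,
#'   `waveform` (microvolts), `peak_amplitude` (the trough value, negative)
#'   and `trough_index`.
#' @examples
#' tpl <- make_templates(5, 64, c(-120, -50), rng_seed = 1)
#' sapply(tpl, function(t) min(t$waveform))
#' @export
make_templates <- function(n_neurons, template_length = 64L,
                           amplitude_range = c(-120, -50), rng_seed = 1L,
                           min_separation = 0.025, sampling_rate = 20000) {
  if (!is.numeric(n_neurons) || length(n_neurons) != 1L || n_neurons < 1) {
    abort("`n_neurons` must be a positive count.")
  }
  if (!is.numeric(template_length) || length(template_length) != 1L ||
      template_length < 64) {
    abort("`template_length` must be a count >= 64.")
  }
  if (length(amplitude_range) != 2L || any(amplitude_range >= 0)) {
    abort("`amplitude_range` must be two negative values (trough convention).")
  }
  n_neurons <- as.integer(n_neurons)
  template_length <- as.integer(template_length)
  bf <- signal::butter(4L, c(300, 3000) / (sampling_rate / 2), "pass")
  filt_grad_shape <- function(w) {
    # the shape the sorters see: bandpass, trough re-cut, min-max, gradient
    x <- c(rep(0, 256), w, rep(0, 256))
    f <- signal::filtfilt(bf, x)
    tr <- which.min(f)
    w64 <- f[(tr - 20L):(tr + 43L)]
    w64 <- (w64 - min(w64)) / (max(w64) - min(w64))
    diff(w64) / sqrt(63)
  }
  wf_shape <- function(w) {
    w <- (w - min(w)) / (max(w) - min(w))
    w / sqrt(length(w))
  }
  with_seed(rng_seed, {
    t <- seq_len(template_length)
    t0 <- max(2L, round(0.35 * template_length))
    draw_shape <- function() {
      # asymmetric trough + after-hyperpolarisation rebound + optional
      # small pre-spike capacitive bump; unit trough depth
      s1l <- runif(1, 3, 6)            # left trough width (sd), 150-300 us
      s1r <- runif(1, 3, 8)            # right trough width
      reb_frac <- runif(1, 0.1, 0.5)   # rebound fraction of trough depth
      s2 <- runif(1, 4, 20)            # rebound width
      reb_lag <- runif(1, 5, 26)       # trough-to-rebound latency
      pre_frac <- runif(1, 0, 0.4)     # pre-spike bump fraction
      s_pre <- runif(1, 2, 6)
      pre_lag <- runif(1, 4, 12)
      s <- ifelse(t < t0, s1l, s1r)
      w <- -exp(-((t - t0)^2) / (2 * s^2)) +
        reb_frac * exp(-((t - t0 - reb_lag)^2) / (2 * s2^2)) +
        pre_frac * exp(-((t - t0 + pre_lag)^2) / (2 * s_pre^2))
      w / abs(min(w))
    }
    draw_bank <- function() {
      shapes <- list()
      g_acc <- list()
      w_acc <- list()
      max_draws <- 400L
      for (i in seq_len(n_neurons)) {
        ok <- FALSE
        for (try in seq_len(max_draws)) {
          w <- draw_shape()
          g <- filt_grad_shape(w)
          ws <- wf_shape(w)
          far <- all(vapply(seq_along(g_acc), function(j) {
            sqrt(sum((g - g_acc[[j]])^2)) >= min_separation &&
              sqrt(sum((ws - w_acc[[j]])^2)) > 0.05
          }, logical(1L)))
          if (far) {
            ok <- TRUE
            break
          }
        }
        if (!ok) return(NULL)  # greedy fill stalled; restart the bank
        g_acc[[i]] <- g
        w_acc[[i]] <- ws
        shapes[[i]] <- w
      }
      shapes
    }
    shapes <- NULL
    for (restart in seq_len(50L)) {
      shapes <- draw_bank()
      if (!is.null(shapes)) break
    }
    if (is.null(shapes)) {
      abort("could not draw a template bank with the requested separation.")
    }
    lapply(seq_len(n_neurons), function(i) {
      w <- shapes[[i]]
      amp <- runif(1, min(amplitude_range), max(amplitude_range))
      wv <- w * (amp / min(w))  # trough now exactly `amp`
      structure(
        list(neuron_id = i, waveform = wv, peak_amplitude = amp,
             trough_index = which.min(wv)),
        class = "spike_template"
      )
    })
  })
}

#' Simulation configuration for synthetic extracellular recordings
#'
#' @param n_neurons Number of foreground source neurons.
#' @param firing_rates Per-neuron mean firing rates in Hz (recycled to
#'   `n_neurons`).
#' @param duration Recording duration in seconds. Ignored when
#'   `target_spike_count` is given, in which case the duration is solved as
#'   `target_spike_count / sum(firing_rates)`.
#' @param sampling_rate Sampling rate in Hz.
#' @param noise_sd Standard deviation of the white Gaussian background noise
#'   (microvolts).
#' @param refractory Per-neuron refractory period in seconds; successive
#'   spikes of one neuron are never closer than this.
#' @param target_spike_count Optional expected total spike count across all
#'   neurons.
#' @param bg_rate Total firing rate (Hz) of unlabelled low-amplitude
#'   background units mimicking distant neurons; 0 disables them.
#' @param bg_amplitude_range Trough-amplitude interval for background units.
#' @param seed Integer seed for the simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_neurons = 5L, firing_rates = c(3, 5, 8, 13, 21),
                       duration = 60, sampling_rate = 20000, noise_sd = 10,
                       refractory = 0.002, target_spike_count = NULL,
                       bg_rate = 0, bg_amplitude_range = c(-30, -15),
                       seed = 1L) {
  stop_if_not_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  if (any(firing_rates < 0)) abort("`firing_rates` must be >= 0.")
  if (refractory < 0) abort("`refractory` must be >= 0.")
  firing_rates <- rep_len(firing_rates, n_neurons)
  if (!is.null(target_spike_count)) {
    stop_if_not_scalar_number(target_spike_count, "target_spike_count",
                              positive = TRUE)
    if (sum(firing_rates) <= 0) {
      abort("`target_spike_count` needs a positive total firing rate.")
    }
    duration <- target_spike_count / sum(firing_rates)
  }
  structure(
    list(n_neurons = as.integer(n_neurons), firing_rates = firing_rates,
         duration = duration, sampling_rate = sampling_rate,
         noise_sd = noise_sd, refractory = refractory,
         target_spike_count = target_spike_count, bg_rate = bg_rate,
         bg_amplitude_range = bg_amplitude_range, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Spike times (seconds) of one unit: a refractory-compensated renewal process.
# Gaps are refractory + Exp(r') with r' = r / (1 - r * refractory), so the
# mean inter-spike interval is exactly 1 / r and the realized count over a
# duration matches the Poisson expectation r * duration.
sim_spike_times <- function(rate, duration, refractory) {
  if (rate <= 0) return(numeric(0))
  if (rate * refractory >= 1) {
    abort("firing rate incompatible with refractory period (rate * refractory >= 1).")
  }
  r_adj <- rate / (1 - rate * refractory)
  n_guess <- ceiling(rate * duration + 4 * sqrt(rate * duration) + 10)
  gaps <- refractory + rexp(n_guess, r_adj)
  times <- cumsum(gaps)
  while (times[length(times)] < duration) {
    gaps <- refractory + rexp(n_guess, r_adj)
    times <- c(times, times[length(times)] + cumsum(gaps))
  }
  times[times < duration]
}

#' Simulate a ground-truthed extracellular recording
#'
#' Builds a single-channel recording as white Gaussian noise plus spike
#' templates inserted at renewal-process spike times (exponential gaps offset
#' by the refractory period, rate-compensated so the empirical rate matches
#' the configured rate). Overlapping spikes superpose linearly. Every
#' inserted foreground spike is recorded in the ground truth with its trough
#' sample index and neuron label; optional background units are inserted but
#' never labelled, mimicking distant-neuron activity.
#'
#' @param templates List of `spike_template` (from [make_templates()]).
#' @param config A [sim_config()].
#' @return A list with components `recording` (a `raw_recording`: `samples`,
#'   `sampling_rate`, `channel_id`) and `truth` (a `ground_truth`:
#'   `spike_times` trough sample indices, `labels`, `n_neurons`,
#'   `sampling_rate`, `duration`).
#' @examples
#' tpl <- make_templates(2, 64, c(-80, -80), rng_seed = 1)
#' out <- simulate_recording(tpl, sim_config(n_neurons = 2, duration = 2,
#'                                           firing_rates = c(5, 5)))
#' length(out$truth$spike_times)
#' @export
simulate_recording <- function(templates, config = sim_config()) {
  if (length(templates) == 0L) abort("`templates` must be non-empty.")
  fs <- config$sampling_rate
  n <- as.integer(round(config$duration * fs))
  rates <- rep_len(config$firing_rates, length(templates))
  with_seed(config$seed, {
    samples <- rnorm(n, 0, config$noise_sd)
    all_idx <- integer(0)
    all_lab <- integer(0)
    for (k in seq_along(templates)) {
      tpl <- templates[[k]]
      st <- sim_spike_times(rates[k], config$duration, config$refractory)
      idx <- as.integer(round(st * fs)) + 1L
      L <- length(tpl$waveform)
      lo <- idx - tpl$trough_index + 1L
      keep <- lo >= 1L & (lo + L - 1L) <= n
      idx <- idx[keep]; lo <- lo[keep]
      for (j in seq_along(lo)) {
        rng <- lo[j]:(lo[j] + L - 1L)
        samples[rng] <- samples[rng] + tpl$waveform
      }
      all_idx <- c(all_idx, idx)
      all_lab <- c(all_lab, rep.int(tpl$neuron_id, length(idx)))
    }
    if (config$bg_rate > 0) {
      bg_tpl <- make_templates(8L, length(templates[[1L]]$waveform),
                               config$bg_amplitude_range,
                               rng_seed = config$seed + 104729L)
      for (tpl in bg_tpl) {
        st <- sim_spike_times(config$bg_rate / length(bg_tpl),
                              config$duration, config$refractory)
        idx <- as.integer(round(st * fs)) + 1L
        L <- length(tpl$waveform)
        lo <- idx - tpl$trough_index + 1L
        keep <- lo >= 1L & (lo + L - 1L) <= n
        for (j in which(keep)) {
          rng <- lo[j]:(lo[j] + L - 1L)
          samples[rng] <- samples[rng] + tpl$waveform
        }
      }
    }
    ord <- order(all_idx)
    recording <- structure(
      list(samples = samples, sampling_rate = fs, channel_id = "sim"),
      class = "raw_recording"
    )
    truth <- structure(
      list(spike_times = all_idx[ord], labels = all_lab[ord],
           n_neurons = length(templates), sampling_rate = fs,
           duration = config$duration),
      class = "ground_truth"
    )
    list(recording = recording, truth = truth)
  })
}

#' Generate a benchmark suite of simulated recordings
#'
#' Produces `n_sets` independent ground-truthed recordings emulating the
#' Small (~100,000 spikes) or Large (~1,100,000 spikes) benchmark size
#' classes, optionally scaled down by `scale_factor` for desk-scale runs.
#' Each set draws a fresh 5-neuron template bank and uses a per-set seed
#' derived deterministically from `rng_seed`, so identical arguments yield
#' bitwise-identical suites. Low-amplitude background units are included to
#' emulate distant-neuron activity.
#'
#' @param size_class `"small"` (target 100,000 spikes) or `"large"`
#'   (target 1,100,000 spikes).
#' @param n_sets Number of independent sets (default 10).
#' @param scale_factor Fraction in (0, 1] applied to the target spike count.
#' @param rng_seed Integer master seed.
#' @param n_neurons Source neurons per set.
#' @param noise_sd Background noise sd in microvolts.
#' @return A list of `n_sets` elements, each a list with `recording` and
#'   `truth` as in [simulate_recording()].
#' @export
make_benchmark_suite <- function(size_class = c("small", "large"),
                                 n_sets = 10L, scale_factor = 1,
                                 rng_seed = 1L, n_neurons = 5L,
                                 noise_sd = 10) {
  size_class <- match.arg(size_class)
  if (n_sets < 1) abort("`n_sets` must be >= 1.")
  if (scale_factor <= 0 || scale_factor > 1) {
    abort("`scale_factor` must be in (0, 1].")
  }
  target <- switch(size_class, small = 1e5, large = 1.1e6) * scale_factor
  lapply(seq_len(n_sets), function(i) {
    set_seed <- as.integer(rng_seed) * 1000L + i
    tpl <- make_templates(n_neurons, 64L, c(-120, -50), rng_seed = set_seed)
    cfg <- sim_config(
      n_neurons = n_neurons,
      firing_rates = c(3, 5, 8, 13, 21),
      sampling_rate = 20000, noise_sd = noise_sd, refractory = 0.002,
      target_spike_count = target,
      bg_rate = 40, bg_amplitude_range = c(-30, -15),
      seed = set_seed
    )
    simulate_recording(tpl, cfg)
  })
}

#' Simulate a fluorescence calcium trace coupled to a spike train
#'
#' Builds a per-frame ROI mean-intensity series as a photobleaching
#' polynomial baseline plus one unit-amplitude exponential-decay calcium
#' transient per ground-truth spike, plus white Gaussian noise. Used to
#' ground-truth the calcium analysis chain.
#'
#' @param truth A `ground_truth` (or NULL/empty for a spike-free trace).
#' @param frame_interval Seconds per imaging frame (default 0.0125: 10 ms
#'   exposure plus readout at 3x3 binning).
#' @param kernel_tau Decay time constant of the calcium transient, seconds.
#' @param bleach_coeffs Polynomial coefficients (ascending powers of time in
#'   seconds) of the bleaching baseline.
#' @param noise_sd Gaussian noise sd, intensity units.
#' @param n_frames Number of frames; defaults to the truth's duration.
#' @param rng_seed Integer seed.
#' @return A `calcium_trace`: `intensities`, `frame_interval`, `roi_id`.
#' @export
simulate_calcium_trace <- function(truth = NULL, frame_interval = 0.0125,
                                   kernel_tau = 0.4,
                                   bleach_coeffs = c(100, -0.05),
                                   noise_sd = 0.02, n_frames = NULL,
                                   rng_seed = 1L) {
  stop_if_not_scalar_number(frame_interval, "frame_interval", positive = TRUE)
  stop_if_not_scalar_number(kernel_tau, "kernel_tau", positive = TRUE)
  spike_s <- if (is.null(truth) || length(truth$spike_times) == 0L) {
    numeric(0)
  } else {
    (truth$spike_times - 1L) / truth$sampling_rate
  }
  if (is.null(n_frames)) {
    dur <- if (!is.null(truth)) truth$duration else 10
    n_frames <- as.integer(ceiling(dur / frame_interval))
  }
  tt <- (seq_len(n_frames) - 1L) * frame_interval
  base <- rep(0, n_frames)
  for (p in seq_along(bleach_coeffs)) {
    base <- base + bleach_coeffs[p] * tt^(p - 1L)
  }
  sig <- rep(0, n_frames)
  for (s in spike_s) {
    i0 <- as.integer(ceiling(s / frame_interval)) + 1L
    if (i0 > n_frames) next
    k <- exp(-(tt[i0:n_frames] - s) / kernel_tau)
    sig[i0:n_frames] <- sig[i0:n_frames] + k
  }
  noise <- if (noise_sd > 0) {
    with_seed(rng_seed, rnorm(n_frames, 0, noise_sd))
  } else {
    rep(0, n_frames)
  }
  structure(
    list(intensities = base + sig + noise, frame_interval = frame_interval,
         roi_id = "sim"),
    class = "calcium_trace"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> channel %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d spikes from %d neurons over %.1f s\n",
              length(x$spike_times), x$n_neurons, x$duration))
  invisible(x)
}
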