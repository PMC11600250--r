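test_that("bleach correction is exact on polynomials and preserves identity", {
  n <- 2000
  tt <- seq_len(n)
  y <- 100 - 0.01 * tt + 2e-6 * tt^2 - 1e-10 * tt^3
  tr <- calcium_trace(y)
  cor <- bleach_correct(tr, order = 10)
  expect_lt(max(abs(cor$residuals)), 1e-6 * diff(range(y)))

  # constant trace
  cor0 <- bleach_correct(calcium_trace(rep(7, 200)), order = 10)
  expect_true(all(cor0$residuals == 0))

  # reconstruction identity holds exactly
  set.seed(2)
  y2 <- 50 + cumsum(rnorm(500))
  cor2 <- bleach_correct(calcium_trace(y2), order = 10)
  expect_identical(cor2$residuals + cor2$fitted_baseline, y2)

  expect_error(bleach_correct(calcium_trace(rnorm(10)), order = 10),
               "length")
})

test_that("calcium spike detection finds prominent peaks only", {
  set.seed(6)
  # flat noise below prominence: empty
  flat <- bleach_correct(calcium_trace(rnorm(2000, 100, 0.5)), order = 10)
  expect_identical(nrow(detect_calcium_spikes(flat, prominence_mult = 6)),
                   0L)

  # one clean bump: exactly one spike at the apex
  y <- rep(100, 1000)
  y[480:520] <- 100 + 5 * exp(-((480:520 - 500)^2) / 50)
  one <- bleach_correct(calcium_trace(y + rnorm(1000, 0, 0.05)), order = 3)
  pk <- detect_calcium_spikes(one, prominence_mult = 5)
  expect_identical(nrow(pk), 1L)
  expect_lt(abs(pk$frame - 500), 3)
  expect_gt(pk$amplitude, 0)
})

test_that("spike detection commutes with adding a low-order polynomial", {
  set.seed(9)
  truth <- structure(list(spike_times = as.integer(seq(20000, 380000,
                                                       length.out = 18)),
                          labels = rep(1L, 18), n_neurons = 1L,
                          sampling_rate = 20000, duration = 20),
                     class = "ground_truth")
  tr <- simulate_calcium_trace(truth, frame_interval = 0.0125,
                               kernel_tau = 0.3, bleach_coeffs = 0,
                               noise_sd = 0.1, rng_seed = 2)
  base <- detect_calcium_spikes(bleach_correct(tr), prominence_mult = 4)

  tt <- (seq_along(tr$intensities) - 1) * tr$frame_interval
  shifted <- calcium_trace(tr$intensities + 30 - 0.8 * tt + 0.01 * tt^2,
                           frame_interval = tr$frame_interval)
  shifted_pk <- detect_calcium_spikes(bleach_correct(shifted),
                                      prominence_mult = 4)
  expect_identical(shifted_pk$frame, base$frame)
})

test_that("simulated calcium spikes are recovered at SNR 8", {
  set.seed(1)
  spike_frames <- sort(sample(200:19000, 20))
  truth <- structure(list(spike_times = as.integer(spike_frames * 250),
                          labels = rep(1L, 20), n_neurons = 1L,
                          sampling_rate = 20000, duration = 250),
                     class = "ground_truth")
  tr <- simulate_calcium_trace(truth, frame_interval = 0.0125,
                               kernel_tau = 0.4,
                               bleach_coeffs = c(100, -0.05),
                               noise_sd = 1 / 8, rng_seed = 3)
  pk <- detect_calcium_spikes(bleach_correct(tr), prominence_mult = 4)
  mm <- match_events(pk$onset_frame, spike_frames + 1L, window = 4)
  expect_gte(mm$recall, 0.95)
  expect_lte(mm$n_false_positives, 1L)
  # parameter recovery: onset times within one frame of injected times
  expect_true(all(mm$pairs$distance <= 1))
})

test_that("delta-F/F scales fluorescence by the basal intensity", {
  f0_tr <- calcium_trace(rep(20, 100))
  expect_true(all(delta_f_over_f(f0_tr)$dff == 0))

  y <- rep(20, 100)
  y[50] <- 21
  d <- delta_f_over_f(calcium_trace(y))
  expect_equal(d$dff[50], 0.05, tolerance = 1e-12)

  y2 <- rep(20, 100)
  y2[10] <- 19
  expect_lt(delta_f_over_f(calcium_trace(y2))$dff[10], 0)

  expect_error(delta_f_over_f(calcium_trace(rep(-5, 50))), "positive")
})

test_that("trace alignment counts co-occurring events within tolerance", {
  ca <- tibble::tibble(frame = 1:5,
                       time_s = c(10, 20, 30, 40, 50),
                       amplitude = rep(1, 5))
  al0 <- align_traces(c(10, 20, 30, 40, 50), ca, offset = 0, tolerance = 1)
  expect_identical(al0$n_co_occurring, 5L)

  # calcium started 0.6 s after the ephys clock
  ca_shift <- ca
  ca_shift$time_s <- ca$time_s + 0.6
  al <- align_traces(c(10, 20, 30, 40, 50), ca_shift, offset = 0.6,
                     tolerance = 1)
  expect_identical(al$n_co_occurring, 5L)
  expect_equal(max(abs(al$events$delta_s)), 0, tolerance = 1e-9)

  al_far <- align_traces(c(100, 200), ca, offset = 0, tolerance = 1)
  expect_identical(al_far$n_co_occurring, 0L)
})

test_that("population summaries normalise activity to day 1", {
  mk_events <- function(day, rate, ids = paste0("r", 1:3), dur = 100) {
    do.call(rbind, lapply(ids, function(u) {
      k <- rate * dur
      tibble::tibble(group = "ctrl", day = day, id = u,
                     time_s = seq(0.5, dur - 0.5, length.out = k))
    }))
  }
  # identical activity on all days: all relative values 1
  ev <- dplyr::bind_rows(lapply(1:3, function(d) mk_events(d, 2)))
  ps <- population_summary(ev, duration = 100)
  expect_true(all(abs(ps$relative - 1) < 1e-9))

  # programmed halving of the rate
  ev2 <- dplyr::bind_rows(lapply(1:4, function(d) mk_events(d, 16 / 2^(d - 1))))
  ps2 <- population_summary(ev2, duration = 100)
  rates <- ps2$relative[ps2$metric == "rate"]
  expect_equal(rates, c(1, 0.5, 0.25, 0.125), tolerance = 1e-9)

  # single-unit day: rate SEM is zero, synchronicity flagged undefined
  ev3 <- mk_events(1, 2, ids = "solo")
  ps3 <- population_summary(ev3, duration = 100)
  expect_identical(ps3$sem_relative[ps3$metric == "rate"], 0)
  expect_true(is.na(ps3$value[ps3$metric == "synchronicity"]))

  ev_bad <- mk_events(2, 2)
  expect_error(population_summary(ev_bad, duration = 100), "day-1")
})
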