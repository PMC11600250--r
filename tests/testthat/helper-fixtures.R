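# Shared fixtures, built once per test run.

# Two well-separated Gaussian blobs in feature space.
make_blobs <- function(n_per = 150L, d = 63L, gap = 8, seed = 42L) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per * d, 0), n_per, d),
    matrix(rnorm(n_per * d, gap / sqrt(d) * 4), n_per, d)
  )
  list(X = X, labels = rep(1:2, each = n_per))
}

# Small end-to-end simulated set used by several sorter tests: 5 neurons,
# ~1500 spikes, SNR ~12-15.
.sim_cache <- new.env(parent = emptyenv())

small_sorted_fixture <- function() {
  if (!is.null(.sim_cache$fix)) {
    return(.sim_cache$fix)
  }
  tpl <- make_templates(5, 64, c(-120, -100), rng_seed = 1)
  cfg <- sim_config(firing_rates = c(0.8, 1.2, 1.6, 2, 2.4),
                    target_spike_count = 1500, seed = 1, noise_sd = 8)
  sim <- simulate_recording(tpl, cfg)
  pipe <- detect_pipeline(sim$recording)
  mm <- match_events(pipe$trough_index, sim$truth, window = 10)
  true_of_pred <- rep(NA_integer_, length(pipe$trough_index))
  true_of_pred[mm$pairs$pred_pos] <- sim$truth$labels[mm$pairs$truth_pos]
  .sim_cache$fix <- list(sim = sim, pipe = pipe, matching = mm,
                         true_of_pred = true_of_pred,
                         scored = !is.na(true_of_pred))
  .sim_cache$fix
}

# Fast training configuration for unit tests.
fast_config <- function(seed = 7L, pretrain_epochs = 10L,
                        finetune_iterations = 120L, batch_size = 128L,
                        ...) {
  train_config(pretrain_epochs = pretrain_epochs,
               finetune_iterations = finetune_iterations,
               batch_size = batch_size, seed = seed, ...)
}

hungarian_brute_force <- function(C) {
  # maximise trace over one-to-one assignments by enumeration (square C)
  s <- nrow(C)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(s))) {
    best <- max(best, sum(C[cbind(seq_len(s), p)]))
  }
  best
}
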