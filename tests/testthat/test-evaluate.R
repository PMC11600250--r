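test_that("the assignment solver matches brute-force enumeration", {
  set.seed(17)
  for (trial in 1:20) {
    s <- sample(2:5, 1)
    C <- matrix(sample(0:50, s * s, replace = TRUE), s, s)
    assign_col <- spikedec:::hungarian_min(max(C) - C)
    got <- sum(C[cbind(seq_len(s), assign_col)])
    expect_equal(got, hungarian_brute_force(C))
  }
})

test_that("matched accuracy is optimal over cluster-neuron assignments", {
  # a permutation relabelling scores 1.0
  truth <- sample(1:5, 300, replace = TRUE)
  perm <- c(3, 5, 1, 2, 4)
  expect_equal(match_accuracy(perm[truth], truth)$accuracy, 1.0)

  # one predicted class against uniform truth over 5 classes
  truth5 <- rep(1:5, each = 20)
  expect_equal(match_accuracy(rep(1L, 100), truth5)$accuracy, 0.2)

  # worked confusion [[40,10],[5,45]]: best assignment scores 85/100
  pred <- c(rep(1, 50), rep(2, 50))
  tru <- c(rep(1, 40), rep(2, 10), rep(1, 5), rep(2, 45))
  rep_acc <- match_accuracy(pred, tru)
  expect_equal(rep_acc$accuracy, 0.85)
  expect_identical(sum(rep_acc$confusion), 100)

  # optimality: never below the identity assignment
  set.seed(3)
  p <- sample(1:4, 500, replace = TRUE)
  t2 <- sample(1:4, 500, replace = TRUE)
  id_acc <- mean(p == t2)
  expect_gte(match_accuracy(p, t2)$accuracy, id_acc)

  # invariance under relabelling of predictions
  relab <- c(4, 1, 3, 2)
  expect_equal(match_accuracy(relab[p], t2)$accuracy,
               match_accuracy(p, t2)$accuracy)

  expect_error(match_accuracy(integer(0), integer(0)), "non-empty")
  expect_error(match_accuracy(1:3, 1:4), "equal length")
})

test_that("event matching pairs detections one-to-one within the window", {
  truth <- structure(list(spike_times = c(100L, 200L, 300L), labels = 1:3,
                          n_neurons = 3L, sampling_rate = 20000,
                          duration = 1),
                     class = "ground_truth")
  m1 <- match_events(c(100L, 200L, 300L), truth, window = 10)
  expect_identical(m1$n_matched, 3L)
  expect_identical(m1$n_misses, 0L)

  m2 <- match_events(integer(0), truth, window = 10)
  expect_identical(m2$n_misses, 3L)
  expect_equal(m2$recall, 0)

  # uniform shift of 3 samples still pairs everything
  m3 <- match_events(c(103L, 203L, 303L), truth, window = 10)
  expect_identical(m3$n_matched, 3L)
  expect_true(all(m3$pairs$distance == 3))

  # two detections cannot claim one truth: the closer one wins
  m4 <- match_events(c(100L, 102L), truth, window = 10)
  expect_identical(m4$n_matched, 1L)
  expect_identical(m4$pairs$pred_pos, 1L)
  expect_identical(m4$n_false_positives, 1L)
})

test_that("relative improvement is the normalised percent difference", {
  expect_equal(relative_improvement(0.80, 0.80), 0)
  expect_equal(relative_improvement(0.88, 0.80), 10)
  # antisymmetry around equal accuracies
  expect_equal(relative_improvement(0.7, 0.8),
               -relative_improvement(0.9, 0.8), tolerance = 1e-12)
  expect_error(relative_improvement(0.5, 0), "> 0")
})

test_that("spike rates follow count over duration", {
  tr <- spike_train(seq(0.25, 49.75, length.out = 100), duration = 50)
  expect_equal(spike_rate(tr), 2)
  expect_equal(spike_rate(spike_train(numeric(0), 10)), 0)
  set.seed(8)
  times <- cumsum(rexp(2000, 5))
  tr2 <- spike_train(times[times < 200], 200)
  expect_lt(abs(spike_rate(tr2) - 5), 3 * sqrt(1000) / 200)
})

test_that("mutual information matches its plug-in formula and properties", {
  # construct trains with joint bin counts [[40,10],[10,40]] over 100 bins
  a_bins <- 1:50
  b_bins <- c(1:40, 51:60)
  tr_a <- spike_train(a_bins - 0.5, 100)
  tr_b <- spike_train(b_bins - 0.5, 100)
  mi <- mutual_information(tr_a, tr_b, bin_width = 1)
  h02 <- -(0.2 * log2(0.2) + 0.8 * log2(0.8))
  expect_equal(mi, 1 - h02, tolerance = 1e-9)

  # symmetry and self-information
  expect_equal(mutual_information(tr_b, tr_a, 1), mi, tolerance = 1e-12)
  h_a <- 1  # a occupies half the bins
  expect_equal(mutual_information(tr_a, tr_a, 1), h_a, tolerance = 1e-9)

  # independent Poisson trains have near-zero plug-in MI
  set.seed(4)
  t1 <- cumsum(rexp(500, 2.5)); t1 <- t1[t1 < 200]
  t2 <- cumsum(rexp(500, 2.5)); t2 <- t2[t2 < 200]
  mi_ind <- mutual_information(spike_train(t1, 200), spike_train(t2, 200),
                               bin_width = 0.02)
  expect_lt(mi_ind, 0.01)
  expect_gte(mi_ind, 0)

  expect_error(mutual_information(tr_a, tr_b, bin_width = 0), "bin_width")
  expect_error(mutual_information(spike_train(0.1, 0.5), tr_b, 1),
               "complete bins")
})

test_that("the benchmark harness produces the contracted table shapes", {
  suite <- make_benchmark_suite("small", n_sets = 2, scale_factor = 0.008,
                                rng_seed = 3)
  cfg <- fast_config(pretrain_epochs = 4, finetune_iterations = 40)
  bm <- run_benchmark(suite, sorters = c("ensemble", "deepae", "dec"),
                      K = 5, config = cfg)
  expect_identical(nrow(bm$per_set), 6L)  # 2 sets x 3 sorters
  ref_rows <- bm$per_set[bm$per_set$model == "ensemble", ]
  expect_true(all(ref_rows$improvement_pct == 0))
  expect_identical(nrow(bm$summary), 3L)
  expect_true(all(bm$per_set$accuracy >= 0 & bm$per_set$accuracy <= 1))

  # reference-only benchmark: all improvements are zero
  bm0 <- run_benchmark(suite[1], sorters = "ensemble", K = 5, config = cfg)
  expect_true(all(bm0$per_set$improvement_pct == 0))

  # reproducibility at fixed seeds
  bm2 <- run_benchmark(suite, sorters = c("ensemble", "deepae", "dec"),
                       K = 5, config = cfg)
  expect_identical(bm$per_set, bm2$per_set)

  expect_error(run_benchmark(suite, sorters = "dec", reference = "ensemble"),
               "reference")
  expect_error(run_benchmark(list()), "non-empty")
})

test_that("tidiers expose labels and summaries as tibbles", {
  blobs <- make_blobs(n_per = 80)
  r <- deep_ae_sort(blobs$X, network_spec(c(63, 16, 4)), fast_config(),
                    K = 2)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 160L)
  expect_true(all(td$confidence > 0 & td$confidence <= 1))
  gl <- glance(r)
  expect_identical(gl$method, "deepae")
  expect_identical(gl$n_spikes, 160L)
})
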