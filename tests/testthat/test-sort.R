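test_that("soft assignment matches the Student's-t kernel exactly", {
  # squared distances 1 and 3 at alpha = 1: q = (1/2, 1/4) -> (2/3, 1/3)
  z <- matrix(c(0, 0), 1, 2)
  mu <- rbind(c(1, 0), c(sqrt(3), 0))
  Q <- soft_assign(z, mu, alpha = 1)
  expect_equal(as.numeric(Q), c(2 / 3, 1 / 3), tolerance = 1e-9)

  # point on a centroid, others far away
  mu2 <- rbind(c(0, 0), c(10, 0), c(0, 10))
  Q2 <- soft_assign(z, mu2, alpha = 1)
  expect_gt(Q2[1, 1], 0.98)

  # equidistant: symmetric assignment
  Q3 <- soft_assign(matrix(c(0.5, 0), 1, 2), rbind(c(0, 0), c(1, 0)))
  expect_equal(as.numeric(Q3), c(0.5, 0.5), tolerance = 1e-12)

  expect_error(soft_assign(z, mu, alpha = 0), "alpha")
  expect_error(soft_assign(z, mu[1, , drop = FALSE]), "2 centroids")
})

test_that("target distribution sharpens assignments as q^2 / f", {
  # one-hot rows stay one-hot
  Q <- diag(3)
  expect_equal(target_distribution(Q), diag(3), tolerance = 1e-12)

  # single row: P = Q (algebraic identity)
  q <- matrix(c(0.2, 0.3, 0.5), 1, 3)
  expect_equal(target_distribution(q), q, tolerance = 1e-12)

  # uniform Q stays uniform
  Qu <- matrix(1 / 4, 6, 4)
  expect_equal(target_distribution(Qu), Qu, tolerance = 1e-12)

  # brute-force oracle on a random row-stochastic matrix
  set.seed(5)
  Qr <- matrix(runif(12), 4, 3)
  Qr <- Qr / rowSums(Qr)
  f <- colSums(Qr)
  Pexp <- Qr^2 / rep(f, each = 4)
  Pexp <- Pexp / rowSums(Pexp)
  expect_equal(target_distribution(Qr), Pexp, tolerance = 1e-9)

  # a zero column is excluded and reported
  Qz <- cbind(Qr, 0)
  Pz <- target_distribution(Qz)
  expect_identical(attr(Pz, "dropped_clusters"), 4L)
  expect_true(all(Pz[, 4] == 0))
})

test_that("autoencoder pretraining reduces loss and separates blobs", {
  blobs <- make_blobs()
  cfg <- fast_config()
  ae <- pretrain_autoencoder(blobs$X, network_spec(c(63, 32, 2)), cfg)
  expect_lt(ae$final_loss, ae$initial_loss)

  # same seed, same losses
  ae2 <- pretrain_autoencoder(blobs$X, network_spec(c(63, 32, 2)), cfg)
  expect_identical(ae$final_loss, ae2$final_loss)

  # constant dataset reconstructs almost perfectly
  Xc <- matrix(1, 200, 63) + 0  # identical rows
  aec <- pretrain_autoencoder(Xc, network_spec(c(63, 16, 2)),
                              fast_config(pretrain_epochs = 20))
  expect_lt(aec$final_loss, 1e-3)

  # latent embedding separates the blobs: between-centroid distance
  # exceeds within-blob spread (silhouette-like criterion)
  z <- encode(ae, blobs$X)
  z1 <- z[blobs$labels == 1, ]
  z2 <- z[blobs$labels == 2, ]
  between <- sqrt(sum((colMeans(z1) - colMeans(z2))^2))
  within <- mean(c(sqrt(rowSums(sweep(z1, 2, colMeans(z1))^2)),
                   sqrt(rowSums(sweep(z2, 2, colMeans(z2))^2))))
  expect_gt(between, 2 * within)

  expect_error(pretrain_autoencoder(blobs$X[, 1:10], network_spec()),
               "dimension")
})

test_that("DEC clusters separated blobs perfectly and respects contracts", {
  blobs <- make_blobs()
  cfg <- fast_config()
  r <- train_dec(blobs$X, network_spec(c(63, 32, 5)), cfg, K = 2)
  expect_equal(match_accuracy(r$labels, blobs$labels)$accuracy, 1.0)
  expect_true(all(abs(rowSums(r$soft_assignments) - 1) < 1e-6))
  expect_identical(r$labels, max.col(r$soft_assignments))

  # near-1 tolerance stops at the first convergence check
  cfg_stop <- fast_config(tol = 0.999)
  r2 <- train_dec(blobs$X, network_spec(c(63, 32, 5)), cfg_stop, K = 2)
  expect_true(r2$converged)
  expect_lte(r2$n_iterations, ceiling(nrow(blobs$X) / cfg_stop$batch_size))

  expect_error(train_dec(blobs$X, K = nrow(blobs$X) + 1), "exceed")
})

test_that("IDEC with zero clustering weight equals continued AE training", {
  blobs <- make_blobs(n_per = 120)
  cfg <- fast_config(gamma = 0, pretrain_epochs = 4,
                     finetune_iterations = 40)
  spec <- network_spec(c(63, 32, 8))
  ae <- pretrain_autoencoder(blobs$X, spec, cfg)
  r <- train_idec(blobs$X, spec, cfg, K = 2, pretrained = ae)
  ae2 <- continue_autoencoder(ae, blobs$X, iterations = r$n_iterations,
                              config = cfg)
  for (l in seq_along(ae2$net$W)) {
    expect_identical(r$model$ae$net$W[[l]], ae2$net$W[[l]])
    expect_identical(r$model$ae$net$b[[l]], ae2$net$b[[l]])
  }
})

test_that("IDEC solves the blob fixture and matches DEC's contracts", {
  blobs <- make_blobs()
  cfg <- fast_config(gamma = 0.1)
  r <- train_idec(blobs$X, network_spec(c(63, 32, 5)), cfg, K = 2)
  expect_equal(match_accuracy(r$labels, blobs$labels)$accuracy, 1.0)
  expect_true(all(abs(rowSums(r$soft_assignments) - 1) < 1e-6))
})

test_that("DeepAE sorter is deterministic and exact on point clusters", {
  set.seed(10)
  centers <- matrix(rnorm(3 * 63, sd = 5), 3, 63)
  X <- centers[rep(1:3, each = 60), ] + rnorm(180 * 63, sd = 0.01)
  truth <- rep(1:3, each = 60)
  cfg <- fast_config()
  r <- deep_ae_sort(X, network_spec(c(63, 32, 5)), cfg, K = 3)
  expect_equal(match_accuracy(r$labels, truth)$accuracy, 1.0)
  r2 <- deep_ae_sort(X, network_spec(c(63, 32, 5)), cfg, K = 3)
  expect_identical(r$labels, r2$labels)
})

test_that("the AE ensemble baseline needs >= 2 members and solves blobs", {
  blobs <- make_blobs()
  expect_error(ae_ensemble_sort(blobs$X, n_members = 1), "n_members")
  r <- ae_ensemble_sort(blobs$X, config = fast_config(), K = 2)
  expect_equal(match_accuracy(r$labels, blobs$labels)$accuracy, 1.0)
  expect_identical(nrow(r$model$members), 5L)
  expect_true(all(c("member", "latent_dim", "final_loss") %in%
                    names(r$model$members)))
})

test_that("DEC and IDEC do not degrade a good k-means initialisation", {
  blobs <- make_blobs()
  cfg <- fast_config()
  spec <- network_spec(c(63, 32, 5))
  ae <- pretrain_autoencoder(blobs$X, spec, cfg)
  z <- encode(ae, blobs$X)
  set.seed(cfg$seed + 1)
  km <- kmeans(z, 2, nstart = 10)
  acc_init <- match_accuracy(km$cluster, blobs$labels)$accuracy
  for (fit in list(train_dec(blobs$X, spec, cfg, K = 2, pretrained = ae),
                   train_idec(blobs$X, spec, cfg, K = 2, pretrained = ae))) {
    acc_fit <- match_accuracy(fit$labels, blobs$labels)$accuracy
    expect_gte(acc_fit, acc_init - 0.05)
  }
})

test_that("over-clustering isolates injected artifacts", {
  # genuine spikes: two shape families; artifacts: square pulses
  set.seed(21)
  base1 <- sin(seq(0, 3 * pi, length.out = 63))
  base2 <- cos(seq(0, 2 * pi, length.out = 63))
  X <- rbind(
    matrix(rep(base1, each = 200), 200) + rnorm(200 * 63, sd = 0.05),
    matrix(rep(base2, each = 200), 200) + rnorm(200 * 63, sd = 0.05)
  )
  art <- matrix(rep(c(rep(4, 20), rep(-4, 20), rep(4, 23)), each = 40), 40) +
    rnorm(40 * 63, sd = 0.05)
  Xa <- rbind(X, art)
  is_art <- c(rep(FALSE, 400), rep(TRUE, 40))

  flt0 <- overcluster_artifact_filter(Xa, K_over = 8,
                                      config = fast_config())
  expect_true(all(flt0$keep))          # empty noise set keeps everything
  expect_identical(nrow(flt0$class_means), 8L)

  tab <- table(flt0$labels[is_art])
  noise_ids <- as.integer(names(tab)[tab / sum(tab) >= 0.1])
  flt <- overcluster_artifact_filter(Xa, K_over = 8,
                                     noise_class_ids = noise_ids,
                                     config = fast_config())
  expect_gte(mean(!flt$keep[is_art]), 0.9)   # >= 90% of artifacts removed
  expect_lte(mean(!flt$keep[!is_art]), 0.1)  # genuine spikes retained

  expect_error(
    overcluster_artifact_filter(Xa, K_over = 8, noise_class_ids = 99,
                                config = fast_config()),
    "1..K_over"
  )
})

test_that("a forced 20-class sort emits exactly 20 classes", {
  fix <- small_sorted_fixture()
  flt <- overcluster_artifact_filter(fix$pipe$features, K_over = 20,
                                     config = fast_config())
  expect_identical(sort(unique(flt$labels)), 1:20)
  expect_identical(nrow(flt$class_means), 20L)
})
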