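#' Autoencoder architecture specification
#'
#' Describes the encoder side of a symmetric fully-connected autoencoder:
#' `layer_sizes` runs from the input (feature) dimension down to the latent
#' dimension; the decoder mirrors it. Hidden layers use the rectified-linear
#' activation; the latent and output layers are linear.
#'
#' @param layer_sizes Integer vector from input size to latent size
#'   (default `c(63, 256, 64, 10)` for 63-d gradient features).
#' @param activation Hidden activation; only `"relu"` is supported.
#' @return A `network_spec`.
#' @export
network_spec <- function(layer_sizes = c(63L, 256L, 64L, 10L),
                         activation = "relu") {
  if (length(layer_sizes) < 2L || any(layer_sizes < 1)) {
    abort("`layer_sizes` must be >= 2 sizes, all >= 1.")
  }
  if (!identical(activation, "relu")) abort("only 'relu' is supported.")
  structure(
    list(layer_sizes = as.integer(layer_sizes), activation = activation,
         latent_dim = as.integer(layer_sizes[length(layer_sizes)])),
    class = "network_spec"
  )
}

#' Training configuration for the autoencoder sorters
#'
#' @param pretrain_epochs Autoencoder pretraining epochs.
#' @param finetune_iterations Maximum clustering fine-tune minibatch steps
#'   (DEC/IDEC).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam learning rate for pretraining; fine-tuning uses
#'   `finetune_lr`.
#' @param finetune_lr Adam learning rate for the clustering fine-tune phase.
#' @param alpha Degrees of freedom of the Student's-t soft-assignment kernel
#'   (default 1).
#' @param gamma Weight of the clustering loss relative to reconstruction in
#'   IDEC (default 0.1).
#' @param update_interval Fine-tune iterations between refreshes of the
#'   auxiliary target distribution; default one epoch-equivalent
#'   (`ceiling(n / batch_size)`).
#' @param tol Stop fine-tuning when the fraction of spikes changing cluster
#'   between consecutive target refreshes falls below this (in (0, 1)).
#' @param seed Integer seed; all randomness in a sorter flows from it.
#' @return A `train_config`.
#' @export
train_config <- function(pretrain_epochs = 30L, finetune_iterations = 600L,
                         batch_size = 256L, learning_rate = 1e-3,
                         finetune_lr = 5e-4, alpha = 1, gamma = 0.1,
                         update_interval = NULL, tol = 0.001, seed = 1L) {
  if (gamma < 0) abort("`gamma` must be >= 0.")
  if (alpha <= 0) abort("`alpha` must be > 0.")
  if (tol <= 0 || tol >= 1) abort("`tol` must be in (0, 1).")
  if (pretrain_epochs < 1 || finetune_iterations < 1 || batch_size < 1) {
    abort("epoch/iteration/batch counts must be >= 1.")
  }
  structure(
    list(pretrain_epochs = as.integer(pretrain_epochs),
         finetune_iterations = as.integer(finetune_iterations),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, finetune_lr = finetune_lr,
         alpha = alpha, gamma = gamma, update_interval = update_interval,
         tol = tol, seed = as.integer(seed)),
    class = "train_config"
  )
}

# Build the full symmetric autoencoder net from an encoder spec.
build_autoencoder_net <- function(spec) {
  enc_sizes <- spec$layer_sizes
  sizes <- c(enc_sizes, rev(enc_sizes)[-1L])
  L <- length(sizes) - 1L
  enc_depth <- length(enc_sizes) - 1L
  act <- rep("relu", L)
  act[enc_depth] <- "linear"  # latent layer
  act[L] <- "linear"          # reconstruction output
  net <- mlp_init(sizes, act)
  net$enc_depth <- enc_depth
  net
}

scale_stats <- function(X) {
  list(center = mean(X), scale = max(stats::sd(X), .Machine$double.eps))
}

apply_scaling <- function(X, sc) (X - sc$center) / sc$scale

# One pass of minibatch Adam training of the full autoencoder on
# pre-scaled features; consumes RNG only through sample.int per iteration.
ae_train_iters <- function(net, opt, Xs, iterations, batch_size, lr) {
  n <- nrow(Xs)
  d <- ncol(Xs)
  bs <- min(batch_size, n)
  loss <- numeric(iterations)
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, bs)
    Xb <- Xs[idx, , drop = FALSE]
    A <- mlp_forward(net, Xb)
    err <- A[[length(A)]] - Xb
    loss[it] <- mean(err^2)
    g <- mlp_backward(net, A, 2 * err / (bs * d))
    up <- adam_step(net, g, opt, lr)
    net <- up$net
    opt <- up$st
  }
  list(net = net, opt = opt, loss = loss)
}

recon_error <- function(net, Xs) {
  A <- mlp_forward(net, Xs)
  mean((A[[length(A)]] - Xs)^2)
}

#' Pretrain a deep autoencoder on spike features
#'
#' Trains a symmetric fully-connected autoencoder to minimise mean-squared
#' reconstruction error with minibatch Adam. Features are standardised
#' internally (global mean/sd); the scaling is stored in the returned object
#' and re-applied by [encode()]. Deterministic given `config$seed`.
#'
#' @param features n x d numeric matrix (d must match the spec input size).
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @return An `autoencoder` object with the trained network, the feature
#'   scaling, and a loss history tibble.
#' @export
pretrain_autoencoder <- function(features, spec = network_spec(),
                                 config = train_config()) {
  features <- as.matrix(features)
  if (ncol(features) != spec$layer_sizes[1L]) {
    abort(sprintf("feature dimension %d does not match spec input size %d.",
                  ncol(features), spec$layer_sizes[1L]))
  }
  with_seed(config$seed, {
    sc <- scale_stats(features)
    Xs <- apply_scaling(features, sc)
    net <- build_autoencoder_net(spec)
    loss0 <- recon_error(net, Xs)
    opt <- adam_new(net)
    n <- nrow(Xs)
    iters_per_epoch <- max(1L, ceiling(n / config$batch_size))
    hist <- numeric(config$pretrain_epochs)
    for (ep in seq_len(config$pretrain_epochs)) {
      res <- ae_train_iters(net, opt, Xs, iters_per_epoch,
                            config$batch_size, config$learning_rate)
      net <- res$net
      opt <- res$opt
      hist[ep] <- mean(res$loss)
    }
    structure(
      list(net = net, opt = opt, spec = spec, scaling = sc,
           initial_loss = loss0, final_loss = recon_error(net, Xs),
           history = tibble::tibble(epoch = seq_len(config$pretrain_epochs),
                                    loss = hist)),
      class = "autoencoder"
    )
  })
}

#' Encode features into the autoencoder's latent space
#'
#' @param ae An `autoencoder` from [pretrain_autoencoder()].
#' @param features n x d matrix on the original feature scale.
#' @return n x latent_dim matrix of latent codes.
#' @export
encode <- function(ae, features) {
  Xs <- apply_scaling(as.matrix(features), ae$scaling)
  net <- ae$net
  A <- Xs
  n <- nrow(Xs)
  for (l in seq_len(net$enc_depth)) {
    A <- A %*% net$W[[l]] + rep(net$b[[l]], each = n)
    if (net$act[l] == "relu") A <- pmax(A, 0)
  }
  A
}

#' Student's-t soft cluster assignment
#'
#' Computes the row-stochastic soft-assignment matrix Q of latent codes to
#' cluster centroids under the Student's-t kernel:
#' `q_ij` is proportional to `(1 + ||z_i - mu_j||^2 / alpha)^(-(alpha+1)/2)`.
#'
#' @param latent n x d matrix of latent codes.
#' @param centroids K x d matrix of cluster centroids.
#' @param alpha Kernel degrees of freedom (> 0, default 1).
#' @return n x K row-stochastic matrix.
#' @export
soft_assign <- function(latent, centroids, alpha = 1) {
  if (alpha <= 0) abort("`alpha` must be > 0.")
  latent <- as.matrix(latent)
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2L) abort("need at least 2 centroids.")
  D2 <- sq_dist(latent, centroids)
  Qu <- (1 + D2 / alpha)^(-(alpha + 1) / 2)
  Qu / rowSums(Qu)
}

# Pairwise squared Euclidean distances between rows of A (n x d) and
# rows of B (K x d).
sq_dist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  D2 <- an + rep(bn, each = nrow(A)) - 2 * tcrossprod(A, B)
  pmax(D2, 0)
}

#' Auxiliary target distribution for deep embedded clustering
#'
#' Sharpens a soft assignment Q into the self-training target P with
#' `p_ij` proportional to `q_ij^2 / f_j`, `f_j = sum_i q_ij` (the soft
#' cluster frequency), rows renormalised to 1. Clusters with zero total
#' assignment are excluded from the sharpening and reported via the
#' `dropped_clusters` attribute.
#'
#' @param Q n x K row-stochastic matrix (from [soft_assign()]).
#' @return n x K row-stochastic target matrix.
#' @export
target_distribution <- function(Q) {
  Q <- as.matrix(Q)
  f <- colSums(Q)
  zero <- f <= 0
  P <- Q^2 / rep(pmax(f, .Machine$double.xmin), each = nrow(Q))
  if (any(zero)) P[, zero] <- 0
  P <- P / rowSums(P)
  if (any(zero)) attr(P, "dropped_clusters") <- which(zero)
  P
}

# Clustering-loss gradients (KL(P||Q) under the Student's-t kernel) for a
# minibatch; returns dL/dz (nb x d) and dL/dmu (K x d), mean-per-sample.
dec_gradients <- function(zb, mu, Pb, alpha) {
  nb <- nrow(zb)
  D2 <- sq_dist(zb, mu)
  Wk <- 1 / (1 + D2 / alpha)
  Qu <- Wk^((alpha + 1) / 2)
  Qb <- Qu / rowSums(Qu)
  coef <- ((alpha + 1) / alpha) * Wk * (Pb - Qb)
  g_z <- (zb * rowSums(coef) - coef %*% mu) / nb
  g_mu <- -(crossprod(coef, zb) - colSums(coef) * mu) / nb
  list(g_z = g_z, g_mu = g_mu, Qb = Qb)
}

# Adam state for a single matrix (the centroids).
madam_new <- function(M) list(m = array(0, dim(M)), v = array(0, dim(M)),
                              t = 0L)
madam_step <- function(M, g, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  M <- M - lr * (st$m / (1 - beta1^st$t)) /
    (sqrt(st$v / (1 - beta2^st$t)) + eps)
  list(M = M, st = st)
}

# Shared DEC/IDEC fine-tuning loop. `retain_decoder = FALSE` gives DEC
# (encoder-only, pure KL objective); TRUE gives IDEC (full autoencoder,
# L = L_recon + gamma * L_cluster). RNG is consumed only by sample.int, one
# call per iteration, so IDEC with gamma = 0 follows the exact minibatch
# sequence of continued autoencoder training under the same seed.
dec_finetune <- function(ae, Xs, mu, config, retain_decoder, gamma) {
  net <- ae$net
  enc_depth <- net$enc_depth
  n <- nrow(Xs)
  d <- ncol(Xs)
  bs <- min(config$batch_size, n)
  ui <- config$update_interval %||% max(1L, ceiling(n / bs))
  alpha <- config$alpha
  lr <- config$finetune_lr
  opt <- adam_new(net)
  mopt <- madam_new(mu)
  enc_layers <- if (retain_decoder) length(net$W) else enc_depth
  last_labels <- NULL
  P_full <- NULL
  converged <- FALSE
  hist_it <- integer(0)
  hist_change <- numeric(0)
  n_done <- 0L
  encode_all <- function() {
    A <- Xs
    for (l in seq_len(enc_depth)) {
      A <- A %*% net$W[[l]] + rep(net$b[[l]], each = n)
      if (net$act[l] == "relu") A <- pmax(A, 0)
    }
    A
  }
  for (it in seq_len(config$finetune_iterations)) {
    if ((it - 1L) %% ui == 0L) {
      z_all <- encode_all()
      Qf <- soft_assign(z_all, mu, alpha)
      labs <- max.col(Qf, ties.method = "first")
      if (!is.null(last_labels)) {
        chg <- mean(labs != last_labels)
        hist_it <- c(hist_it, it - 1L)
        hist_change <- c(hist_change, chg)
        if (chg < config$tol) {
          converged <- TRUE
          break
        }
      }
      last_labels <- labs
      P_full <- target_distribution(Qf)
    }
    idx <- sample.int(n, bs)
    Xb <- Xs[idx, , drop = FALSE]
    Pb <- P_full[idx, , drop = FALSE]
    if (retain_decoder) {
      A <- mlp_forward(net, Xb)
      zb <- A[[enc_depth + 1L]]
      cg <- dec_gradients(zb, mu, Pb, alpha)
      delta <- 2 * (A[[length(A)]] - Xb) / (bs * d)
      L <- length(net$W)
      gW <- vector("list", L)
      gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        if (net$act[l] == "relu") delta <- delta * (A[[l + 1L]] > 0)
        gW[[l]] <- crossprod(A[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1L) {
          delta <- tcrossprod(delta, net$W[[l]])
          if (l - 1L == enc_depth) delta <- delta + gamma * cg$g_z
        }
      }
      g <- list(W = gW, b = gb)
      up <- adam_step(net, g, opt, lr)
      net <- up$net
      opt <- up$st
      mup <- madam_step(mu, gamma * cg$g_mu, mopt, lr)
      mu <- mup$M
      mopt <- mup$st
    } else {
      enc <- list(W = net$W[seq_len(enc_depth)],
                  b = net$b[seq_len(enc_depth)],
                  act = net$act[seq_len(enc_depth)])
      A <- mlp_forward(enc, Xb)
      zb <- A[[enc_depth + 1L]]
      cg <- dec_gradients(zb, mu, Pb, alpha)
      g <- mlp_backward(enc, A, cg$g_z)
      # pad gradients with zeros for the (frozen, unused) decoder layers
      gW <- c(g$W, lapply(net$W[-seq_len(enc_depth)], function(w) w * 0))
      gb <- c(g$b, lapply(net$b[-seq_len(enc_depth)], function(b) b * 0))
      up <- adam_step(net, list(W = gW, b = gb), opt, lr)
      net <- up$net
      opt <- up$st
      mup <- madam_step(mu, cg$g_mu, mopt, lr)
      mu <- mup$M
      mopt <- mup$st
    }
    n_done <- it
  }
  net_out <- net
  ae$net <- net_out
  z_all <- encode_all()
  Qf <- soft_assign(z_all, mu, alpha)
  list(ae = ae, mu = mu, Q = Qf,
       labels = max.col(Qf, ties.method = "first"),
       converged = converged, n_iterations = n_done,
       history = tibble::tibble(iteration = hist_it,
                                label_change = hist_change))
}

sort_result <- function(method, labels, Q, model, history, converged = NA,
                        n_iterations = NA_integer_) {
  structure(
    list(method = method, labels = as.integer(labels), soft_assignments = Q,
         model = model, history = history, K = ncol(Q),
         converged = converged, n_iterations = n_iterations),
    class = "sort_result"
  )
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("<sort_result> %s: %d spikes into %d clusters%s\n", x$method,
              length(x$labels), x$K,
              if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

# k-means with restarts; Hartigan-Wong can fail its quick-transfer stage on
# large near-duplicate-rich inputs, in which case rerun with MacQueen.
kmeans_robust <- function(x, K, nstart = 10L) {
  warned <- FALSE
  res <- withCallingHandlers(
    kmeans(x, K, nstart = nstart, iter.max = 100L),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (warned) {
    res <- suppressWarnings(
      kmeans(x, K, nstart = nstart, iter.max = 200L,
             algorithm = "MacQueen")
    )
  }
  res
}

# Common front half of DEC/IDEC/DeepAE: pretrain (or reuse), encode, k-means
# init of the centroids. Seeding layout: pretraining consumes the RNG first,
# k-means runs under seed+1, the fine-tune loop under seed+2.
sorter_setup <- function(features, spec, config, K, pretrained) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (K > n) abort("`K` cannot exceed the number of spikes.")
  if (K < 2) abort("`K` must be >= 2.")
  ae <- pretrained %||% pretrain_autoencoder(features, spec, config)
  Xs <- apply_scaling(features, ae$scaling)
  z <- encode(ae, features)
  km <- with_seed(config$seed + 1L, kmeans_robust(z, K))
  list(ae = ae, Xs = Xs, z = z, km = km, n = n)
}

#' Deep Embedded Clustering (DEC) spike sorter
#'
#' Pretrains a deep autoencoder on the gradient features, discards the
#' decoder, initialises K cluster centroids by k-means on the latent codes,
#' and then alternates between refreshing the auxiliary target distribution
#' and minibatch gradient steps on the KL divergence between target and
#' Student's-t soft assignments, updating encoder weights and centroids
#' jointly. Stops when the fraction of spikes changing cluster falls below
#' `config$tol` or the iteration budget is exhausted.
#'
#' @param features n x d matrix of preprocessed spike features.
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param K Number of clusters (source neurons).
#' @param pretrained Optional pre-fitted `autoencoder` to reuse.
#' @return A `sort_result` with hard labels, the soft-assignment matrix Q,
#'   the fitted model (encoder + centroids) and a training history.
#' @export
train_dec <- function(features, spec = network_spec(),
                      config = train_config(), K = 5L, pretrained = NULL) {
  s <- sorter_setup(features, spec, config, K, pretrained)
  ft <- with_seed(config$seed + 2L,
                  dec_finetune(s$ae, s$Xs, s$km$centers, config,
                               retain_decoder = FALSE, gamma = 0))
  sort_result("dec", ft$labels, ft$Q,
              model = list(ae = ft$ae, centroids = ft$mu,
                           alpha = config$alpha),
              history = ft$history, converged = ft$converged,
              n_iterations = ft$n_iterations)
}

#' Improved Deep Embedded Clustering (IDEC) spike sorter
#'
#' As [train_dec()], but the decoder is retained and the fine-tuning
#' objective is the joint loss `L = L_reconstruction + gamma * L_clustering`,
#' preserving local structure in the embedding while sharpening clusters.
#' With `gamma = 0` the parameter-update path reduces exactly to continued
#' autoencoder training (the clustering loss contributes nothing).
#'
#' @inheritParams train_dec
#' @return A `sort_result`.
#' @export
train_idec <- function(features, spec = network_spec(),
                       config = train_config(), K = 5L, pretrained = NULL) {
  s <- sorter_setup(features, spec, config, K, pretrained)
  ft <- with_seed(config$seed + 2L,
                  dec_finetune(s$ae, s$Xs, s$km$centers, config,
                               retain_decoder = TRUE, gamma = config$gamma))
  sort_result("idec", ft$labels, ft$Q,
              model = list(ae = ft$ae, centroids = ft$mu,
                           alpha = config$alpha, gamma = config$gamma),
              history = ft$history, converged = ft$converged,
              n_iterations = ft$n_iterations)
}

#' Continue plain autoencoder training after pretraining
#'
#' Runs further minibatch reconstruction-only Adam steps from a pretrained
#' autoencoder, consuming the RNG exactly as the IDEC fine-tune loop does.
#' With equal seeds, `train_idec(gamma = 0)` and this function follow
#' identical weight trajectories.
#'
#' @param ae An `autoencoder`.
#' @param features Feature matrix on the original scale.
#' @param iterations Number of minibatch steps.
#' @param config A [train_config()] (`finetune_lr`, `batch_size`, `seed`).
#' @return The updated `autoencoder`.
#' @export
continue_autoencoder <- function(ae, features, iterations,
                                 config = train_config()) {
  Xs <- apply_scaling(as.matrix(features), ae$scaling)
  with_seed(config$seed + 2L, {
    opt <- adam_new(ae$net)
    res <- ae_train_iters(ae$net, opt, Xs, iterations, config$batch_size,
                          config$finetune_lr)
    ae$net <- res$net
    ae$final_loss <- recon_error(ae$net, Xs)
    ae
  })
}

#' Deep autoencoder + k-means (DeepAE) spike sorter
#'
#' Pretrains the deep autoencoder, embeds all spikes into the latent space,
#' and clusters the latent codes with k-means. Soft assignments are defined
#' against the k-means centroids via the Student's-t kernel.
#'
#' @inheritParams train_dec
#' @return A `sort_result`.
#' @export
deep_ae_sort <- function(features, spec = network_spec(),
                         config = train_config(), K = 5L,
                         pretrained = NULL) {
  s <- sorter_setup(features, spec, config, K, pretrained)
  Q <- soft_assign(s$z, s$km$centers, config$alpha)
  sort_result("deepae", s$km$cluster, Q,
              model = list(ae = s$ae, centroids = s$km$centers,
                           alpha = config$alpha),
              history = s$ae$history, converged = TRUE,
              n_iterations = 0L)
}

#' Autoencoder-ensemble baseline spike sorter
#'
#' Trains several shallow autoencoders with distinct seeds and latent
#' dimensions, concatenates their latent codes into one embedding, and
#' clusters the concatenation with k-means. Serves as the normalisation
#' reference in the benchmark.
#'
#' @param features n x d feature matrix.
#' @param n_members Number of ensemble members (>= 2; default 5).
#' @param latent_dims Latent dimension per member (recycled).
#' @param hidden Hidden-layer width of each shallow member.
#' @param config A [train_config()].
#' @param K Number of clusters.
#' @param member_epochs Pretraining epochs per shallow member (default 15;
#'   the single-hidden-layer members plateau earlier than the deep net).
#' @return A `sort_result`; `model$members` holds per-member latent
#'   diagnostics (latent dim, final reconstruction loss).
#' @export
ae_ensemble_sort <- function(features, n_members = 5L,
                             latent_dims = c(8L, 10L, 12L, 10L, 8L),
                             hidden = 128L, config = train_config(),
                             K = 5L, member_epochs = 15L) {
  if (n_members < 2) abort("an ensemble needs `n_members` >= 2.")
  features <- as.matrix(features)
  d <- ncol(features)
  latent_dims <- rep_len(latent_dims, n_members)
  zs <- vector("list", n_members)
  diag <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    spec_m <- network_spec(c(d, hidden, latent_dims[m]))
    cfg_m <- config
    cfg_m$pretrain_epochs <- as.integer(member_epochs)
    cfg_m$seed <- config$seed + 100L * m
    ae <- pretrain_autoencoder(features, spec_m, cfg_m)
    zs[[m]] <- encode(ae, features)
    diag[[m]] <- tibble::tibble(member = m, latent_dim = latent_dims[m],
                                final_loss = ae$final_loss)
  }
  Z <- do.call(cbind, zs)
  km <- with_seed(config$seed + 7L, kmeans_robust(Z, K))
  Q <- soft_assign(Z, km$centers, config$alpha)
  sort_result("ensemble", km$cluster, Q,
              model = list(centroids = km$centers,
                           members = dplyr::bind_rows(diag),
                           alpha = config$alpha),
              history = dplyr::bind_rows(diag), converged = TRUE,
              n_iterations = 0L)
}

#' Dispatch a sorter by name
#'
#' @param features Feature matrix.
#' @param method One of `"ensemble"`, `"deepae"`, `"dec"`, `"idec"`.
#' @param spec,config,K Passed to the sorter.
#' @return A `sort_result`.
#' @export
sort_features <- function(features,
                          method = c("ensemble", "deepae", "dec", "idec"),
                          spec = network_spec(), config = train_config(),
                          K = 5L) {
  method <- match.arg(method)
  switch(method,
    ensemble = ae_ensemble_sort(features, config = config, K = K),
    deepae = deep_ae_sort(features, spec, config, K),
    dec = train_dec(features, spec, config, K),
    idec = train_idec(features, spec, config, K)
  )
}

#' Over-clustering artifact filter
#'
#' Sorts all available spikes into a deliberately large number of classes
#' (20 or more) so that artifacts concentrate in their own classes, then
#' removes the classes the analyst has marked as noise. Per-class mean
#' waveforms are returned to support that manual decision.
#'
#' @param features n x d feature matrix of all spikes.
#' @param K_over Number of over-clustering classes (default 20).
#' @param noise_class_ids Integer class ids (1..K_over) to discard; empty
#'   keeps every spike.
#' @param sorter Sorter name passed to [sort_features()] (default
#'   `"deepae"`).
#' @param config A [train_config()].
#' @param waveforms Optional n x 64 waveform matrix; if given, class means
#'   are computed on waveforms rather than features.
#' @return A list with `keep` (logical mask over spikes), `labels`
#'   (over-clustering class per spike) and `class_means` (K_over x d matrix).
#' @export
overcluster_artifact_filter <- function(features, K_over = 20L,
                                        noise_class_ids = integer(0),
                                        sorter = "deepae",
                                        config = train_config(),
                                        waveforms = NULL) {
  if (K_over < 2) abort("`K_over` must be >= 2.")
  res <- sort_features(features, method = sorter, config = config,
                       K = K_over)
  if (length(noise_class_ids) &&
      (any(noise_class_ids < 1) || any(noise_class_ids > K_over))) {
    abort("`noise_class_ids` must reference classes in 1..K_over.")
  }
  base <- if (is.null(waveforms)) as.matrix(features) else as.matrix(waveforms)
  cm <- matrix(NA_real_, K_over, ncol(base))
  for (k in seq_len(K_over)) {
    rows <- res$labels == k
    if (any(rows)) cm[k, ] <- colMeans(base[rows, , drop = FALSE])
  }
  list(keep = !(res$labels %in% noise_class_ids), labels = res$labels,
       class_means = cm)
}
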