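# Compact O(n^3) Hungarian algorithm (shortest augmenting paths with
# potentials) for the assignment problem; minimises total cost of a
# rectangular matrix with nrow <= ncol. Returns the assigned column per row.
hungarian_min <- function(a) {
  n <- nrow(a)
  m <- ncol(a)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m + 1L)      # index 1 is the virtual column 0
  p <- integer(m + 1L)      # p[j+1]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      cur <- a[i0, ] - u[i0] - v[-1L]
      free <- !used[-1L]
      upd <- free & (cur < minv)
      minv[upd] <- cur[upd]
      way[which(upd) + 1L] <- j0
      delta <- min(minv[free])
      j1 <- which(free & minv <= delta)[1L]
      usedj <- which(used)
      rows_used <- p[usedj]
      u[rows_used] <- u[rows_used] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match_col <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1L] > 0L) match_col[p[j + 1L]] <- j
  }
  match_col
}

#' Pair detected events with ground-truth spikes
#'
#' Greedy nearest-neighbour one-to-one pairing of detected spike times
#' (trough sample indices) to ground-truth spike times within a tolerance
#' window. Candidate pairs are considered in order of increasing time
#' difference; each detection and each true spike is used at most once.
#' Unpaired detections are false positives; unpaired truths are misses.
#'
#' @param pred_times Integer sample indices of detections (e.g. trough
#'   indices from [extract_waveforms()]).
#' @param truth A `ground_truth` (or integer vector of true spike indices).
#' @param window Maximum pairing distance in samples (> 0).
#' @return A list: `pairs` (tibble `pred_pos`, `truth_pos`, `distance`),
#'   `n_matched`, `n_misses`, `n_false_positives`, `recall`, `precision`.
#' @export
match_events <- function(pred_times, truth, window = 10L) {
  if (window <= 0) abort("`window` must be > 0.")
  true_times <- if (is.list(truth)) truth$spike_times else as.integer(truth)
  np <- length(pred_times)
  nt <- length(true_times)
  if (np == 0L || nt == 0L) {
    pairs <- tibble::tibble(pred_pos = integer(0), truth_pos = integer(0),
                            distance = integer(0))
    return(list(pairs = pairs, n_matched = 0L, n_misses = nt,
                n_false_positives = np, recall = if (nt) 0 else NA_real_,
                precision = if (np) 0 else NA_real_))
  }
  ord_t <- order(true_times)
  tt <- true_times[ord_t]
  # nearest-two candidate truths per detection
  pos <- findInterval(pred_times, tt)
  cand_lo <- pmax(pos, 1L)
  cand_hi <- pmin(pos + 1L, nt)
  cand <- rbind(
    cbind(seq_len(np), cand_lo),
    cbind(seq_len(np), cand_hi)
  )
  cand <- cand[!duplicated(cand), , drop = FALSE]
  d <- abs(pred_times[cand[, 1L]] - tt[cand[, 2L]])
  keep <- d <= window
  cand <- cand[keep, , drop = FALSE]
  d <- d[keep]
  o <- order(d)
  cand <- cand[o, , drop = FALSE]
  d <- d[o]
  used_p <- rep(FALSE, np)
  used_t <- rep(FALSE, nt)
  sel <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]
    j <- cand[r, 2L]
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- TRUE
      used_t[j] <- TRUE
      sel[r] <- TRUE
    }
  }
  pairs <- tibble::tibble(pred_pos = as.integer(unname(cand[sel, 1L])),
                          truth_pos = as.integer(unname(ord_t[cand[sel, 2L]])),
                          distance = unname(d[sel]))
  n_matched <- nrow(pairs)
  list(pairs = pairs, n_matched = n_matched, n_misses = nt - n_matched,
       n_false_positives = np - n_matched,
       recall = n_matched / nt, precision = n_matched / np)
}

#' Hungarian-matched clustering accuracy
#'
#' Computes unsupervised classification accuracy: the maximum, over
#' one-to-one assignments of predicted clusters to true neurons, of the
#' fraction of spikes whose assigned neuron matches the truth. The optimum
#' is found by the Hungarian algorithm on the confusion matrix.
#'
#' @param pred_labels Integer cluster labels.
#' @param true_labels Integer ground-truth neuron labels (same length).
#' @param scope Scoring scope label carried in the report:
#'   `"matched_only"` (clustering scored on detected spikes paired to truth)
#'   or `"all_truth"` (missed detections counted as errors; the caller adds
#'   the missing truths as unmatched rows).
#' @return An `accuracy_report`: `accuracy`, `assignment` (tibble
#'   cluster -> neuron), `confusion` (clusters x neurons count matrix),
#'   `scope`, `n_scored`.
#' @export
match_accuracy <- function(pred_labels, true_labels,
                           scope = c("matched_only", "all_truth")) {
  scope <- match.arg(scope)
  if (length(pred_labels) == 0L || length(true_labels) == 0L) {
    abort("label vectors must be non-empty.")
  }
  if (length(pred_labels) != length(true_labels)) {
    abort("`pred_labels` and `true_labels` must have equal length.")
  }
  pl <- factor(pred_labels)
  tl <- factor(true_labels)
  C <- table(pl, tl)
  C <- matrix(as.numeric(C), nrow(C), ncol(C),
              dimnames = list(levels(pl), levels(tl)))
  s <- max(nrow(C), ncol(C))
  Cp <- matrix(0, s, s)
  Cp[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  assign_col <- hungarian_min(max(Cp) - Cp)
  matched <- sum(Cp[cbind(seq_len(s), assign_col)])
  n <- length(pred_labels)
  keep <- seq_len(nrow(C))
  assignment <- tibble::tibble(
    cluster = rownames(C),
    neuron = ifelse(assign_col[keep] <= ncol(C),
                    colnames(C)[pmin(assign_col[keep], ncol(C))],
                    NA_character_)
  )
  structure(
    list(accuracy = matched / n, assignment = assignment, confusion = C,
         scope = scope, n_scored = n),
    class = "accuracy_report"
  )
}

#' Relative accuracy improvement over a reference sorter
#'
#' @param acc_model Accuracy of the model of interest (fraction).
#' @param acc_reference Accuracy of the reference (fraction, > 0).
#' @return Percent improvement, `100 * (acc_model - acc_reference) /
#'   acc_reference`.
#' @examples
#' relative_improvement(0.88, 0.80)  # +10
#' @export
relative_improvement <- function(acc_model, acc_reference) {
  if (any(acc_reference <= 0)) abort("`acc_reference` must be > 0.")
  100 * (acc_model - acc_reference) / acc_reference
}

#' Benchmark spike sorters on a simulated suite
#'
#' For every set in a simulated suite: runs the detection chain (bandpass,
#' robust threshold, trough alignment, gradient features), pairs detections
#' with ground truth, runs each sorter with a per-set seed, scores
#' Hungarian-matched accuracy, and computes per-set relative improvements
#' against the reference sorter. Summaries are mean and standard deviation
#' over sets per model.
#'
#' @param suite A list of `list(recording, truth)` sets, e.g. from
#'   [make_benchmark_suite()].
#' @param sorters Character vector of sorter names (see [sort_features()]);
#'   must include `reference`.
#' @param K Number of clusters passed to every sorter.
#' @param spec A [network_spec()] for the deep sorters.
#' @param config A [train_config()]; per-set, per-sorter seeds are derived
#'   from `config$seed`.
#' @param reference Name of the normalisation reference sorter.
#' @param window Detection-to-truth pairing window, samples.
#' @param scope Accuracy scope, see [match_accuracy()]. Under `"all_truth"`
#'   missed ground-truth spikes are scored as errors.
#' @param size_class Optional label stored with the result.
#' @return A `benchmark_result`: `per_set` tibble (set, model, accuracy,
#'   improvement_pct, n_scored, detection_recall), `summary` tibble (model,
#'   mean/sd of accuracy and improvement), `reference`, `scope`,
#'   `size_class`, `failures`.
#' @export
run_benchmark <- function(suite,
                          sorters = c("ensemble", "deepae", "dec", "idec"),
                          K = 5L, spec = network_spec(),
                          config = train_config(), reference = "ensemble",
                          window = 10L,
                          scope = c("matched_only", "all_truth"),
                          size_class = NA_character_) {
  scope <- match.arg(scope)
  if (length(suite) == 0L) abort("`suite` must be non-empty.")
  if (!reference %in% sorters) {
    abort("`sorters` must include the reference sorter.")
  }
  rows <- list()
  failures <- list()
  for (i in seq_along(suite)) {
    set <- suite[[i]]
    pipe <- detect_pipeline(set$recording)
    mm <- match_events(pipe$trough_index, set$truth, window = window)
    true_of_pred <- rep(NA_integer_, length(pipe$trough_index))
    true_of_pred[mm$pairs$pred_pos] <- set$truth$labels[mm$pairs$truth_pos]
    scored <- !is.na(true_of_pred)
    # one pretrained autoencoder per set, shared by the deep sorters
    # (standard DEC/IDEC practice: both start from the same pretrained net)
    shared_ae <- NULL
    if (any(c("deepae", "dec", "idec") %in% sorters)) {
      cfg_pre <- config
      cfg_pre$seed <- config$seed + 1000L * i
      shared_ae <- tryCatch(
        pretrain_autoencoder(pipe$features, spec, cfg_pre),
        error = function(e) NULL
      )
    }
    for (s in sorters) {
      cfg <- config
      cfg$seed <- config$seed + 1000L * i + 97L * match(s, sorters)
      res <- tryCatch(
        switch(s,
          ensemble = ae_ensemble_sort(pipe$features, config = cfg, K = K),
          deepae = deep_ae_sort(pipe$features, spec, cfg, K,
                                pretrained = shared_ae),
          dec = train_dec(pipe$features, spec, cfg, K,
                          pretrained = shared_ae),
          idec = train_idec(pipe$features, spec, cfg, K,
                            pretrained = shared_ae),
          abort(sprintf("unknown sorter '%s'.", s))
        ),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          tibble::tibble(set = i, model = s, message = conditionMessage(res))
        next
      }
      if (scope == "matched_only") {
        rep_acc <- match_accuracy(res$labels[scored], true_of_pred[scored],
                                  scope = scope)
        acc <- rep_acc$accuracy
        n_scored <- rep_acc$n_scored
      } else {
        # missed truths enter as an extra pseudo-cluster never matchable
        missed_idx <- setdiff(seq_along(set$truth$labels),
                              mm$pairs$truth_pos)
        pl <- c(res$labels[scored], rep(0L, length(missed_idx)))
        tl <- c(true_of_pred[scored], set$truth$labels[missed_idx])
        rep_acc <- match_accuracy(pl, tl, scope = scope)
        # spikes in the pseudo-cluster can never agree; accuracy already
        # reflects them through the enlarged denominator
        acc <- rep_acc$accuracy
        n_scored <- rep_acc$n_scored
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        set = i, model = s, accuracy = acc, n_scored = n_scored,
        detection_recall = mm$recall
      )
    }
  }
  per_set <- dplyr::bind_rows(rows)
  ref_acc <- per_set[per_set$model == reference, c("set", "accuracy")]
  names(ref_acc)[2L] <- "ref_accuracy"
  per_set <- dplyr::left_join(per_set, ref_acc, by = "set")
  per_set$improvement_pct <-
    relative_improvement(per_set$accuracy, per_set$ref_accuracy)
  per_set$ref_accuracy <- NULL
  summary <- per_set |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_sets = dplyr::n(),
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = stats::sd(.data$accuracy),
      mean_improvement = mean(.data$improvement_pct),
      sd_improvement = stats::sd(.data$improvement_pct),
      .groups = "drop"
    )
  structure(
    list(per_set = per_set, summary = summary, reference = reference,
         scope = scope, size_class = size_class,
         failures = dplyr::bind_rows(failures)),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d sets, reference = %s, scope = %s\n",
              max(x$per_set$set), x$reference, x$scope))
  print(x$summary)
  invisible(x)
}

#' Construct a spike train
#'
#' @param times Event times in seconds, within `[0, duration]`.
#' @param duration Recording duration, seconds (> 0).
#' @param source Electrode or neuron label.
#' @return A `spike_train`.
#' @export
spike_train <- function(times, duration, source = NA_character_) {
  stop_if_not_scalar_number(duration, "duration", positive = TRUE)
  times <- sort(as.numeric(times))
  if (length(times) && (times[1L] < 0 || times[length(times)] > duration)) {
    abort("`times` must lie within [0, duration].")
  }
  structure(list(times = times, duration = duration, source = source),
            class = "spike_train")
}

#' Mean firing rate of a spike train
#'
#' @param train A [spike_train()].
#' @return Rate in Hz (`count / duration`).
#' @export
spike_rate <- function(train) {
  length(train$times) / train$duration
}

#' Mutual information between two spike trains
#'
#' Synchronicity measure: both trains are binarised into common time bins
#' (1 if the bin holds at least one event) and the plug-in mutual
#' information of the joint 2x2 histogram is computed in bits (log base 2).
#'
#' @param train_a,train_b [spike_train()] objects covering a common
#'   duration (the shorter duration is used).
#' @param bin_width Bin width in seconds (default 20 ms).
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(train_a, train_b, bin_width = 0.02) {
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  dur <- min(train_a$duration, train_b$duration)
  nb <- floor(dur / bin_width)
  if (nb < 1) abort("no complete bins: duration shorter than `bin_width`.")
  binarize <- function(tr) {
    idx <- floor(tr$times / bin_width) + 1
    idx <- idx[idx >= 1 & idx <= nb]
    x <- logical(nb)
    x[idx] <- TRUE
    x
  }
  a <- binarize(train_a)
  b <- binarize(train_b)
  joint <- table(factor(a, levels = c(FALSE, TRUE)),
                 factor(b, levels = c(FALSE, TRUE))) / nb
  pa <- rowSums(joint)
  pb <- colSums(joint)
  mi <- 0
  for (i in 1:2) {
    for (j in 1:2) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log2(joint[i, j] / (pa[i] * pb[j]))
      }
    }
  }
  max(unname(mi), 0)
}
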