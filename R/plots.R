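#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_boxplot
#'   geom_jitter geom_hline labs theme_minimal autoplot facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a sample of aligned spike waveforms
#'
#' Overlays up to `n_max` trough-aligned waveforms with the per-set mean,
#' optionally coloured by sorter label.
#'
#' @param waveforms A `spike_waveforms` object.
#' @param labels Optional integer labels per waveform.
#' @param n_max Maximum number of individual traces drawn.
#' @return A ggplot object.
#' @export
plot_waveforms <- function(waveforms, labels = NULL, n_max = 200L) {
  wf <- waveforms$waveforms
  n <- nrow(wf)
  take <- if (n > n_max) seq.int(1L, n, length.out = n_max) else seq_len(n)
  take <- unique(as.integer(take))
  df <- tibble::tibble(
    spike = rep(take, each = ncol(wf)),
    sample = rep(seq_len(ncol(wf)), length(take)),
    voltage = as.vector(t(wf[take, , drop = FALSE])),
    label = if (is.null(labels)) "all" else
      as.character(rep(labels[take], each = ncol(wf)))
  )
  mean_df <- tibble::tibble(sample = seq_len(ncol(wf)),
                            voltage = colMeans(wf))
  ggplot(df, aes(x = .data$sample, y = .data$voltage,
                 group = .data$spike, colour = .data$label)) +
    geom_line(alpha = 0.2) +
    geom_line(data = mean_df, aes(group = NULL, colour = NULL),
              linewidth = 1) +
    labs(x = "sample (trough at 21)", y = "voltage (µV)",
         colour = "cluster") +
    theme_minimal()
}

#' @export
autoplot.sort_result <- function(object, features = NULL, ...) {
  Q <- object$soft_assignments
  if (!is.null(features)) {
    pc <- stats::prcomp(as.matrix(features), rank. = 2L)
    df <- tibble::tibble(x = pc$x[, 1L], y = pc$x[, 2L],
                         label = factor(object$labels))
    xl <- "PC1"
    yl <- "PC2"
  } else {
    df <- tibble::tibble(x = seq_along(object$labels),
                         y = Q[cbind(seq_len(nrow(Q)), object$labels)],
                         label = factor(object$labels))
    xl <- "spike"
    yl <- "assignment confidence"
  }
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$label)) +
    geom_point(alpha = 0.4, size = 0.8) +
    labs(x = xl, y = yl, colour = "cluster",
         title = sprintf("%s (K = %d)", object$method, object$K)) +
    theme_minimal()
}

#' @export
autoplot.benchmark_result <- function(object, ...) {
  df <- object$per_set[object$per_set$model != object$reference, ]
  ggplot(df, aes(x = .data$model, y = .data$improvement_pct)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, alpha = 0.7) +
    labs(x = NULL,
         y = sprintf("accuracy improvement vs %s (%%)", object$reference),
         title = object$size_class %||% "") +
    theme_minimal()
}

#' Plot a bleach-corrected calcium trace with detected spikes
#'
#' @param corrected A `corrected_trace`.
#' @param spikes Optional `calcium_spikes` tibble to mark.
#' @return A ggplot object.
#' @export
plot_calcium <- function(corrected, spikes = NULL) {
  df <- tibble::tibble(
    time_s = (seq_along(corrected$residuals) - 1L) *
      corrected$frame_interval,
    residual = corrected$residuals
  )
  p <- ggplot(df, aes(x = .data$time_s, y = .data$residual)) +
    geom_line(colour = "grey30", linewidth = 0.3) +
    labs(x = "time (s)", y = "corrected fluorescence (a.u.)") +
    theme_minimal()
  if (!is.null(spikes) && nrow(spikes)) {
    p <- p + geom_point(data = spikes,
                        aes(x = .data$time_s, y = .data$amplitude),
                        colour = "magenta", size = 1.5)
  }
  p
}
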