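#' Write a recording (and optional ground truth) to delimited text
#'
#' The container is a CSV with commented metadata header lines
#' (`# key: value`, carrying the mandatory sampling rate and the channel
#' id) followed by a single `voltage_uv` column. Ground truth, if given, is
#' written to a sidecar `<path>.truth.csv` with columns
#' `spike_time_index,label` and is re-attached by [read_recording()].
#'
#' @param recording A `raw_recording`.
#' @param path Output file path.
#' @param truth Optional `ground_truth`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, truth = NULL) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("# sampling_rate_hz: %.10g", recording$sampling_rate),
    sprintf("# channel_id: %s", recording$channel_id),
    "voltage_uv"
  ), con)
  writeLines(sprintf("%.10g", recording$samples), con)
  if (!is.null(truth)) {
    tp <- paste0(path, ".truth.csv")
    df <- data.frame(spike_time_index = truth$spike_times,
                     label = truth$labels)
    con2 <- file(tp, "w")
    writeLines(c(
      sprintf("# n_neurons: %d", truth$n_neurons),
      sprintf("# sampling_rate_hz: %.10g", truth$sampling_rate),
      sprintf("# duration_s: %.10g", truth$duration)
    ), con2)
    close(con2)
    suppressWarnings(
      write.table(df, tp, sep = ",", row.names = FALSE, col.names = TRUE,
                  quote = FALSE, append = TRUE)
    )
  }
  invisible(path)
}

read_header_meta <- function(path) {
  meta <- list()
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || !startsWith(ln, "#")) break
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  meta
}

#' Read a recording from a delimited-text container
#'
#' Accepts the container written by [write_recording()]: commented header
#' lines with a mandatory `sampling_rate_hz` field, then one voltage column.
#' A `<path>.truth.csv` sidecar, if present, is attached as ground truth.
#' Non-finite samples are rejected with their count reported.
#'
#' @param path File path.
#' @return A `raw_recording`; if ground truth is present it is attached as
#'   attribute `truth`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- read_header_meta(path)
  if (is.null(meta$sampling_rate_hz)) {
    abort("recording header is missing the mandatory 'sampling_rate_hz' field.")
  }
  df <- read.csv(path, comment.char = "#")
  x <- as.numeric(df[[1L]])
  n_bad <- sum(!is.finite(x))
  if (n_bad > 0L) {
    abort(sprintf("recording contains %d non-finite samples.", n_bad))
  }
  rec <- structure(
    list(samples = x, sampling_rate = as.numeric(meta$sampling_rate_hz),
         channel_id = meta$channel_id %||% NA_character_),
    class = "raw_recording"
  )
  tp <- paste0(path, ".truth.csv")
  if (file.exists(tp)) {
    tmeta <- read_header_meta(tp)
    tdf <- read.csv(tp, comment.char = "#")
    attr(rec, "truth") <- structure(
      list(spike_times = as.integer(tdf$spike_time_index),
           labels = as.integer(tdf$label),
           n_neurons = as.integer(tmeta$n_neurons),
           sampling_rate = as.numeric(tmeta$sampling_rate_hz),
           duration = as.numeric(tmeta$duration_s)),
      class = "ground_truth"
    )
  }
  rec
}

#' Write / read a calcium trace as two-column CSV
#'
#' Columns are `frame_time_s` and `intensity`; the frame interval is
#' recovered from the time column on read.
#'
#' @param trace A `calcium_trace`.
#' @param path File path.
#' @return `path` (write) / a `calcium_trace` (read).
#' @export
write_calcium_trace <- function(trace, path) {
  tt <- (seq_along(trace$intensities) - 1L) * trace$frame_interval
  write.csv(data.frame(frame_time_s = tt, intensity = trace$intensities),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calcium_trace
#' @export
read_calcium_trace <- function(path) {
  df <- read.csv(path)
  if (!all(c("frame_time_s", "intensity") %in% names(df))) {
    abort("calcium CSV needs columns frame_time_s, intensity.")
  }
  fi <- if (nrow(df) > 1L) stats::median(diff(df$frame_time_s)) else 0.0125
  calcium_trace(df$intensity, frame_interval = fi,
                roi_id = basename(path))
}

#' Pipeline run configuration
#'
#' A single nested, serialisable configuration for the whole pipeline:
#' detection, sorting, simulation and calcium parameters plus the master
#' seed and output directory. Round-trips exactly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param detection,sorter,simulator,calcium Named lists of parameters
#'   (defaults documented in the respective functions).
#' @param seed Master seed.
#' @param output_dir Output directory for run artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(detection = list(low = 300, high = 3000,
                                        multiplier = 5,
                                        dead_time = 0.0015),
                       sorter = list(layer_sizes = c(63, 256, 64, 10),
                                     K = 5, pretrain_epochs = 15,
                                     finetune_iterations = 600,
                                     batch_size = 256,
                                     learning_rate = 1e-3,
                                     finetune_lr = 5e-4, alpha = 1,
                                     gamma = 0.1, tol = 0.001),
                       simulator = list(n_neurons = 5,
                                        firing_rates = c(3, 5, 8, 13, 21),
                                        sampling_rate = 20000,
                                        noise_sd = 10,
                                        refractory = 0.002),
                       calcium = list(order = 10, prominence_mult = 4,
                                      frame_interval = 0.0125,
                                      tolerance = 1),
                       seed = 1L, output_dir = ".") {
  structure(
    list(detection = detection, sorter = sorter, simulator = simulator,
         calcium = calcium, seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Write a machine-readable run manifest
#'
#' Records the seed, a hash of the configuration and the produced artifact
#' paths, so that a rerun with an identical manifest reproduces identical
#' outputs for the deterministic stages.
#'
#' @param config A `run_config`.
#' @param outputs Character vector of produced file paths.
#' @param path Manifest JSON path.
#' @export
write_manifest <- function(config, outputs, path) {
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    outputs = as.list(outputs),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export a benchmark result to CSV and JSON
#'
#' Writes the per-set long-format table (`set_id`, `model`, `accuracy`,
#' `improvement_pct`) and a JSON summary of per-model means and standard
#' deviations.
#'
#' @param result A `benchmark_result`.
#' @param csv_path,json_path Output paths.
#' @export
write_benchmark <- function(result, csv_path, json_path = NULL) {
  tab <- result$per_set[, c("set", "model", "accuracy", "improvement_pct")]
  names(tab)[1L] <- "set_id"
  write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(reference = result$reference, scope = result$scope,
           size_class = result$size_class, summary = result$summary),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(csv_path)
}
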