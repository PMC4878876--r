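#' Build an electrophysiology trace
#'
#' A trace is a tibble with one row per sample and columns `time_ms`, `value`
#' and `artifact` (logical, `TRUE` for samples inside a stimulus-artifact
#' blanking window). Recording metadata travels in attributes so that the
#' object still pipes like an ordinary data frame.
#'
#' @param time_ms Numeric vector of sample times in ms, uniformly spaced,
#'   strictly increasing.
#' @param value Numeric vector of samples: current in pA for voltage-clamp
#'   traces (outward positive), membrane potential in mV for current-clamp
#'   traces.
#' @param mode `"voltage_clamp"` or `"current_clamp"`.
#' @param stim_times_ms Stimulus onset times in ms (may be empty).
#' @param artifact_blank_ms Duration after each stimulus onset during which
#'   samples are flagged as artifact-contaminated and excluded from
#'   measurements. Default 0.6 ms.
#' @param ground_truth Optional list of generator ground truth (see
#'   [generate_ipsc_train_trace()]).
#' @param meta Optional named list of labels (cell id, sex, genotype,
#'   condition, seed, ...).
#'
#' @return A tibble of class `ephys_trace` with attributes `mode`, `unit`,
#'   `sample_interval_ms`, `stim_times_ms`, `artifact_blank_ms`,
#'   `ground_truth` and `meta`.
#' @export
#' @examples
#' tr <- new_trace(seq(0, 10, by = 0.1), sin(seq(0, 10, by = 0.1)),
#'                 mode = "voltage_clamp")
#' trace_sample_interval(tr)
new_trace <- function(time_ms, value,
                      mode = c("voltage_clamp", "current_clamp"),
                      stim_times_ms = numeric(),
                      artifact_blank_ms = 0.6,
                      ground_truth = NULL,
                      meta = list()) {
  mode <- rlang::arg_match(mode)
  if (length(time_ms) != length(value)) {
    rlang::abort("`time_ms` and `value` must have the same length.",
                 class = "synaptrain_error_bad_trace")
  }
  if (length(time_ms) < 2L) {
    rlang::abort("A trace needs at least two samples.",
                 class = "synaptrain_error_bad_trace")
  }
  dt <- diff(time_ms)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * dt[1]) {
    rlang::abort("`time_ms` must be uniformly spaced and increasing.",
                 class = "synaptrain_error_bad_trace")
  }
  artifact <- rep(FALSE, length(time_ms))
  for (s in stim_times_ms) {
    artifact <- artifact | (time_ms >= s & time_ms < s + artifact_blank_ms)
  }
  out <- tibble::tibble(time_ms = as.numeric(time_ms),
                        value = as.numeric(value),
                        artifact = artifact)
  structure(out,
            class = c("ephys_trace", class(out)),
            mode = mode,
            unit = if (mode == "voltage_clamp") "pA" else "mV",
            sample_interval_ms = dt[1],
            stim_times_ms = as.numeric(stim_times_ms),
            artifact_blank_ms = artifact_blank_ms,
            ground_truth = ground_truth,
            meta = meta)
}

#' Trace metadata accessors
#'
#' @param trace An [new_trace()] object.
#' @return `trace_mode()` the clamp mode; `trace_sample_interval()` the sample
#'   interval in ms; `trace_stim_times()` stimulus onsets in ms;
#'   `trace_ground_truth()` the generator ground-truth list (or `NULL`);
#'   `trace_meta()` the label list.
#' @export
trace_mode <- function(trace) attr(trace, "mode")

#' @rdname trace_mode
#' @export
trace_sample_interval <- function(trace) attr(trace, "sample_interval_ms")

#' @rdname trace_mode
#' @export
trace_stim_times <- function(trace) attr(trace, "stim_times_ms")

#' @rdname trace_mode
#' @export
trace_ground_truth <- function(trace) attr(trace, "ground_truth")

#' @rdname trace_mode
#' @export
trace_meta <- function(trace) attr(trace, "meta")

#' @export
print.ephys_trace <- function(x, ...) {
  dur <- diff(range(x$time_ms))
  cat(sprintf("<ephys_trace> %s, %d samples at %.4g kHz, %.5g ms, %d stimuli\n",
              trace_mode(x), nrow(x), 1 / trace_sample_interval(x), dur,
              length(trace_stim_times(x))))
  NextMethod()
}

# Linear interpolation of the trace at arbitrary times (internal).
trace_value_at <- function(trace, t) {
  stats::approx(trace$time_ms, trace$value, xout = t, rule = 2)$y
}

#' Write / read a trace as CSV with a JSON sidecar
#'
#' The CSV holds `time_ms,value,artifact`; the sidecar (`<path>.json`) holds
#' clamp mode, unit, sample interval, stimulus times, blanking window, labels
#' and any generator ground truth, so a round trip preserves the full object.
#'
#' @param trace An [new_trace()] object.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the reconstructed `ephys_trace`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace[, c("time_ms", "value", "artifact")]),
                   path, row.names = FALSE)
  sidecar <- list(
    mode = trace_mode(trace),
    unit = attr(trace, "unit"),
    sample_interval_ms = trace_sample_interval(trace),
    stim_times_ms = trace_stim_times(trace),
    artifact_blank_ms = attr(trace, "artifact_blank_ms"),
    meta = trace_meta(trace),
    ground_truth = trace_ground_truth(trace)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gt <- side$ground_truth
  if (!is.null(gt)) gt <- lapply(gt, unlist, use.names = FALSE)
  new_trace(df$time_ms, df$value,
            mode = side$mode,
            stim_times_ms = as.numeric(side$stim_times_ms %||% numeric()),
            artifact_blank_ms = side$artifact_blank_ms %||% 0.6,
            ground_truth = gt,
            meta = as.list(side$meta %||% list()))
}

#' Plot a trace
#'
#' @param object An `ephys_trace`.
#' @param ... Unused.
#' @return A ggplot: value against time with stimulus onsets marked.
#' @export
autoplot.ephys_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (ms)",
                  y = sprintf("%s (%s)",
                              if (trace_mode(object) == "voltage_clamp")
                                "Current" else "Potential",
                              attr(object, "unit")))
  st <- trace_stim_times(object)
  if (length(st)) {
    p <- p + ggplot2::geom_vline(xintercept = st, linetype = "dotted",
                                 colour = "grey60", linewidth = 0.2)
  }
  p
}
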