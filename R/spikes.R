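#' Detect action potentials in a current-clamp trace
#'
#' A spike is an upward crossing of `dV/dt >= dvdt_threshold` followed by a
#' voltage peak of at least `peak_min_mV` within `peak_within_ms`; detections
#' closer than `refractory_ms` to the previous accepted spike are discarded.
#' Returned times are the peak times.
#'
#' @param trace A current-clamp [new_trace()].
#' @param dvdt_threshold Onset threshold in mV/ms (default 20).
#' @param peak_min_mV Minimum peak voltage (default -20 mV).
#' @param peak_within_ms Peak must occur within this window after the
#'   threshold crossing (default 2 ms).
#' @param refractory_ms Enforced minimum separation (default 1 ms).
#' @return Numeric vector of spike peak times (ms).
#' @export
detect_spikes <- function(trace, dvdt_threshold = 20, peak_min_mV = -20,
                          peak_within_ms = 2, refractory_ms = 1) {
  if (trace_mode(trace) != "current_clamp") {
    rlang::abort("spike detection needs a current-clamp trace.",
                 class = "synaptrain_error_not_current_clamp")
  }
  dt <- trace_sample_interval(trace)
  v <- trace$value
  t <- trace$time_ms
  dvdt <- c(NA_real_, diff(v) / dt)
  above <- dvdt >= dvdt_threshold
  above[is.na(above)] <- FALSE
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  win <- max(1L, round(peak_within_ms / dt))
  peaks <- numeric(0)
  last <- -Inf
  for (i in onsets) {
    if (t[i] - last < refractory_ms) next
    j <- i:min(i + win, length(v))
    k <- j[which.max(v[j])]
    if (v[k] < peak_min_mV) next
    # skip shoulder crossings inside the same spike
    if (length(peaks) && t[k] - peaks[length(peaks)] < refractory_ms) next
    peaks <- c(peaks, t[k])
    last <- t[i]
  }
  peaks
}

#' Spontaneous firing rate
#'
#' Spike count divided by window duration.
#'
#' @param spike_times_ms Spike times (ms).
#' @param window_ms `c(start, end)` in ms; at least 1 s by default contract.
#' @param min_window_ms Minimum accepted window length (default 1000 ms).
#' @return Rate in spikes/s.
#' @export
spontaneous_rate <- function(spike_times_ms, window_ms,
                             min_window_ms = 1000) {
  dur <- diff(window_ms)
  if (dur < min_window_ms) {
    rlang::abort(sprintf("rate window is %.0f ms; >= %.0f ms required.",
                         dur, min_window_ms),
                 class = "synaptrain_error_window")
  }
  n <- sum(spike_times_ms >= window_ms[1] & spike_times_ms < window_ms[2])
  1000 * n / dur
}

#' Mean action-potential half-width
#'
#' For each spike the amplitude is measured from the dV/dt-threshold voltage
#' to the peak; the half-width is the duration spent above the half-amplitude
#' level, with sub-sample resolution by linear interpolation. The mean over
#' spikes is returned.
#'
#' @param trace A current-clamp [new_trace()].
#' @param spike_times_ms Spike peak times, e.g. from [detect_spikes()].
#' @param dvdt_threshold Threshold used to define the take-off voltage
#'   (default 20 mV/ms).
#' @param min_spikes Minimum number of spikes required (default 10).
#' @return Mean half-width in ms.
#' @export
ap_half_width <- function(trace, spike_times_ms, dvdt_threshold = 20,
                          min_spikes = 10) {
  if (length(spike_times_ms) < min_spikes) {
    rlang::abort(sprintf("half-width needs >= %d spikes.", min_spikes),
                 class = "synaptrain_error_too_few_spikes")
  }
  dt <- trace_sample_interval(trace)
  v <- trace$value
  t <- trace$time_ms
  dvdt <- c(NA_real_, diff(v) / dt)
  widths <- vapply(spike_times_ms, function(ts) {
    i_peak <- which.min(abs(t - ts))
    # walk back to the threshold crossing
    i0 <- i_peak
    back <- max(1L, i_peak - round(3 / dt))
    while (i0 > back && !is.na(dvdt[i0]) && dvdt[i0] >= dvdt_threshold) {
      i0 <- i0 - 1L
    }
    v_thr <- v[i0]
    v_half <- (v_thr + v[i_peak]) / 2
    # rising crossing of v_half
    i_r <- i_peak
    while (i_r > back && v[i_r - 1L] > v_half) i_r <- i_r - 1L
    t_rise <- if (i_r == i_peak) t[i_peak] else {
      stats::approx(v[(i_r - 1L):i_r], t[(i_r - 1L):i_r], xout = v_half)$y
    }
    # falling crossing of v_half
    fwd <- min(length(v), i_peak + round(3 / dt))
    i_f <- i_peak
    while (i_f < fwd && v[i_f + 1L] > v_half) i_f <- i_f + 1L
    t_fall <- if (i_f == i_peak) t[i_peak] else {
      stats::approx(v[i_f:(i_f + 1L)], t[i_f:(i_f + 1L)], xout = v_half)$y
    }
    t_fall - t_rise
  }, numeric(1))
  mean(widths, na.rm = TRUE)
}

#' Post-inhibitory rebound firing, percent change
#'
#' Firing-rate change across an inhibitory stimulus train:
#' `100 * (post - pre) / pre`, with the pre rate measured over the
#' `pre_ms` (default 500 ms) just before train onset and the post rate over
#' the `post_ms` (default 300 ms) just after train end.
#'
#' @param trace A current-clamp [new_trace()].
#' @param train_onset_ms,train_end_ms Train window (ms). Default from the
#'   trace's stimulus times.
#' @param pre_ms,post_ms Window lengths (ms).
#' @param ... Passed to [detect_spikes()].
#' @return A tibble with `pre_rate_Hz`, `post_rate_Hz`, `percent_change`.
#' @export
rebound_percent_change <- function(trace, train_onset_ms = NULL,
                                   train_end_ms = NULL,
                                   pre_ms = 500, post_ms = 300, ...) {
  st <- trace_stim_times(trace)
  gt <- trace_ground_truth(trace)
  train_onset_ms <- train_onset_ms %||% gt$train_onset_ms %||%
    (if (length(st)) min(st) else NULL)
  train_end_ms <- train_end_ms %||% gt$train_end_ms %||%
    (if (length(st)) max(st) + 10 else NULL)
  if (is.null(train_onset_ms) || is.null(train_end_ms)) {
    rlang::abort("train window not specified and not present on the trace.",
                 class = "synaptrain_error_bad_params")
  }
  if (train_onset_ms - pre_ms < min(trace$time_ms) ||
      train_end_ms + post_ms > max(trace$time_ms)) {
    rlang::abort("pre/post windows extend beyond the trace.",
                 class = "synaptrain_error_window")
  }
  spikes <- detect_spikes(trace, ...)
  pre_n <- sum(spikes >= train_onset_ms - pre_ms & spikes < train_onset_ms)
  post_n <- sum(spikes >= train_end_ms & spikes < train_end_ms + post_ms)
  pre_rate <- 1000 * pre_n / pre_ms
  post_rate <- 1000 * post_n / post_ms
  if (pre_rate <= 0) {
    rlang::abort("pre-stimulus rate is zero; percent change undefined.",
                 class = "synaptrain_error_zero_pre_rate")
  }
  tibble::tibble(pre_rate_Hz = pre_rate, post_rate_Hz = post_rate,
                 percent_change = 100 * (post_rate - pre_rate) / pre_rate)
}

#' mGluR1/5-dependent component of rebound firing
#'
#' Cell-by-cell paired difference between the rebound percent change in
#' control and with the group I mGluR blocker, summarised as mean and SEM.
#'
#' @param control,drug Numeric vectors of per-cell rebound percent changes.
#' @param cell_id Cell identifiers aligning the two vectors; both conditions
#'   must cover the same cells.
#' @return A tibble with `mean_component`, `sem_component`, `n`, and the
#'   per-cell differences in a list-column `cell_diffs`.
#' @export
mglur_rebound_component <- function(control, drug, cell_id = NULL) {
  if (is.null(cell_id)) {
    if (length(control) != length(drug)) {
      rlang::abort("unpaired input: control and drug differ in length and no cell ids given.",
                   class = "synaptrain_error_unpaired")
    }
  } else {
    if (length(cell_id) != length(control) ||
        length(cell_id) != length(drug)) {
      rlang::abort("cell_id must align with both conditions.",
                   class = "synaptrain_error_unpaired")
    }
    ord <- order(cell_id)
    control <- control[ord]
    drug <- drug[ord]
  }
  d <- control - drug
  tibble::tibble(mean_component = mean(d),
                 sem_component = if (length(d) > 1) sem(d) else NA_real_,
                 n = length(d),
                 cell_diffs = list(d))
}
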