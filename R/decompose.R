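#' Decompose an evoked train into phasic and tonic components
#'
#' For each stimulus `n` of a high-frequency train the routine measures the
#' peak synaptic current, the tonic (residual) current, and the phasic
#' increment:
#'
#' * baseline: mean current over the `baseline_window_ms` before the first
#'   stimulus;
#' * tonic `T_n`: baseline-subtracted current at the measurement point
#'   `t_n + rise_end_ms + latency_ms` — 8.4 ms after the IPSC peak, which
#'   for a 100-Hz train with the default 1.6-ms peak latency is the onset of
#'   the next stimulus. A median over `+/- median_halfwidth_ms` (artifact
#'   samples excluded) suppresses single-sample noise. `T_0 = 0`.
#' * peak: maximum over `(t_n + blank, t_n + peak_search_end_ms]` above
#'   baseline;
#' * phasic `P_n = peak_n - T_{n-1}`: the current increment attributable to
#'   release evoked by stimulus `n` alone.
#'
#' Percent columns normalise by the first phasic peak, `P_1 = 100`.
#'
#' @param trace A voltage-clamp [new_trace()]; outward currents positive
#'   (use `direction = "inward"` for EPSC trains).
#' @param stim_times_ms Stimulus onsets; defaults to the trace's own.
#' @param latency_ms Tonic read-out latency after the IPSC peak (default
#'   8.4 ms).
#' @param rise_end_ms Stimulus-to-peak time (artifact + rise); default 1.6.
#' @param baseline_window_ms Baseline averaging window before the first
#'   stimulus (default 50 ms).
#' @param peak_search_end_ms End of the peak search window after each
#'   stimulus (default 3.5 ms).
#' @param median_halfwidth_ms Half-width of the tonic median window
#'   (default 0.2 ms).
#' @param direction `"outward"` (IPSC, default) or `"inward"` (EPSC); inward
#'   traces are sign-flipped before decomposition and the reported
#'   amplitudes refer to the flipped (positive) currents.
#'
#' @return A tibble of class `train_decomposition` with columns `stimulus`,
#'   `stim_time_ms`, `peak_pA`, `phasic_pA`, `tonic_pA`, `phasic_pct`,
#'   `tonic_pct`, `tonic_time_ms`, and attributes `baseline_pA`, `p1_pA`,
#'   `latency_ms`, `rise_end_ms`.
#' @export
#' @examples
#' p <- synth_ipsc_params(noise_sd_pA = 0)
#' d <- measure_train(generate_ipsc_train_trace(p, seed = 1))
#' mean_tonic_5_10(d)
measure_train <- function(trace, stim_times_ms = NULL,
                          latency_ms = 8.4,
                          rise_end_ms = 1.6,
                          baseline_window_ms = 50,
                          peak_search_end_ms = 3.5,
                          median_halfwidth_ms = 0.2,
                          direction = c("outward", "inward")) {
  direction <- rlang::arg_match(direction)
  stim_times_ms <- stim_times_ms %||% trace_stim_times(trace)
  if (!length(stim_times_ms)) {
    rlang::abort("no stimulus times supplied.",
                 class = "synaptrain_error_bad_params")
  }
  t <- trace$time_ms
  y <- trace$value
  if (direction == "inward") y <- -y
  ok <- !trace$artifact
  if (min(stim_times_ms) < min(t) + baseline_window_ms ||
      max(stim_times_ms) + rise_end_ms + latency_ms > max(t)) {
    rlang::abort("stimuli (or their measurement points) fall outside the trace.",
                 class = "synaptrain_error_stimulus_outside")
  }
  blank <- attr(trace, "artifact_blank_ms") %||% 0

  base_sel <- t >= stim_times_ms[1] - baseline_window_ms &
    t < stim_times_ms[1]
  baseline <- mean(y[base_sel])
  noise_floor <- 5 * stats::sd(y[base_sel])

  n <- length(stim_times_ms)
  peak <- tonic <- tonic_time <- numeric(n)
  for (i in seq_len(n)) {
    s <- stim_times_ms[i]
    sel_peak <- ok & t > s + blank & t <= s + peak_search_end_ms
    if (!any(sel_peak)) {
      rlang::abort("no unblanked samples in a peak search window.",
                   class = "synaptrain_error_window_too_short")
    }
    peak[i] <- max(y[sel_peak]) - baseline
    tm <- s + rise_end_ms + latency_ms
    sel_t <- ok & abs(t - tm) <= median_halfwidth_ms
    if (!any(sel_t)) {
      rlang::abort("tonic measurement window contains no valid samples.",
                   class = "synaptrain_error_window_too_short")
    }
    tonic[i] <- stats::median(y[sel_t]) - baseline
    tonic_time[i] <- tm
  }
  phasic <- peak - c(0, tonic[-n])
  if (phasic[1] < noise_floor) {
    rlang::abort("first peak does not exceed the baseline noise floor; trace rejected as unevoked.",
                 class = "synaptrain_error_unevoked")
  }
  p1 <- phasic[1]
  out <- tibble::tibble(
    stimulus = seq_len(n),
    stim_time_ms = stim_times_ms,
    peak_pA = peak,
    phasic_pA = phasic,
    tonic_pA = tonic,
    phasic_pct = 100 * phasic / p1,
    tonic_pct = 100 * tonic / p1,
    tonic_time_ms = tonic_time
  )
  structure(out, class = c("train_decomposition", class(out)),
            baseline_pA = baseline, p1_pA = p1,
            latency_ms = latency_ms, rise_end_ms = rise_end_ms,
            direction = direction)
}

#' Mean tonic current over stimuli 5-10
#'
#' Arithmetic mean of the normalised tonic current over stimuli 5 to 10
#' inclusive (six values), the summary used to quantify the group I mGluR
#' contribution to train responses.
#'
#' @param d A [measure_train()] decomposition with at least 10 stimuli.
#' @return Mean tonic current, percent of the first phasic peak.
#' @export
mean_tonic_5_10 <- function(d) {
  if (nrow(d) < 10) {
    rlang::abort("mean_tonic_5_10 needs at least 10 stimuli.",
                 class = "synaptrain_error_too_few_stimuli")
  }
  mean(d$tonic_pct[5:10])
}

#' Steady-state amplitude of a train
#'
#' Mean of the last `n_last` normalised phasic amplitudes — the steady-state
#' depression metric used for EPSC trains.
#'
#' @param d A [measure_train()] decomposition.
#' @param n_last Number of trailing stimuli to average (default 5).
#' @return Steady-state amplitude, percent of the first peak.
#' @export
steady_state_amplitude <- function(d, n_last = 5) {
  if (nrow(d) < n_last) {
    rlang::abort("fewer stimuli than n_last.",
                 class = "synaptrain_error_too_few_stimuli")
  }
  mean(d$phasic_pct[seq.int(nrow(d) - n_last + 1, nrow(d))])
}

#' Group I mGluR contribution to the tonic current
#'
#' The mGluR1/5 contribution is the difference between the mean tonic
#' current for stimuli 5-10 with the mGluR blocker present (drug) and in
#' control solution, combined across cells as an unpaired difference of
#' group means with SEMs propagated in quadrature. A positive value means
#' the blocker unmasked outward tonic current, i.e. an inward mGluR current
#' was present in control.
#'
#' @param control,drug Lists of [measure_train()] decompositions (one per
#'   cell), or numeric vectors of per-cell mean tonic (stimuli 5-10) values.
#' @return A [unpaired_difference()] tibble (`mean_diff` = drug - control).
#' @export
mglur_tonic_difference <- function(control, drug) {
  as_vals <- function(x, lab) {
    if (is.numeric(x)) return(as.numeric(x))
    if (!length(x)) {
      rlang::abort(paste0("empty ", lab, " group."),
                   class = "synaptrain_error_empty_group")
    }
    vapply(x, mean_tonic_5_10, numeric(1))
  }
  vc <- as_vals(control, "control")
  vd <- as_vals(drug, "drug")
  if (!length(vc) || !length(vd)) {
    rlang::abort("both groups must be non-empty.",
                 class = "synaptrain_error_empty_group")
  }
  unpaired_difference(mean(vd), sem(vd), length(vd),
                      mean(vc), sem(vc), length(vc),
                      label_A = "drug", label_B = "control")
}

#' Holding-current amplitude and variance
#'
#' Mean and sample variance of the clamp current over a quiescent window,
#' the summary used to quantify standing (e.g. transporter-block-unmasked)
#' inward currents.
#'
#' @param trace A voltage-clamp [new_trace()].
#' @param window_ms `c(start, end)` in ms; must not contain stimuli.
#' @return A tibble with `mean_pA`, `variance_pA2`, `n`.
#' @export
holding_current_stats <- function(trace, window_ms) {
  sel <- trace$time_ms >= window_ms[1] & trace$time_ms <= window_ms[2] &
    !trace$artifact
  if (sum(sel) < 10) {
    rlang::abort("holding-current window holds fewer than 10 samples.",
                 class = "synaptrain_error_window_too_short")
  }
  st <- trace_stim_times(trace)
  if (any(st >= window_ms[1] & st <= window_ms[2])) {
    rlang::abort("holding-current window must exclude stimuli.",
                 class = "synaptrain_error_bad_params")
  }
  y <- trace$value[sel]
  tibble::tibble(mean_pA = mean(y), variance_pA2 = stats::var(y),
                 n = length(y))
}

#' Pharmacological difference currents on a voltage ramp
#'
#' Averages the sweeps of each condition, resamples the ramp segment on a
#' 4-ms grid, maps grid times to command voltage, and forms the pointwise
#' difference currents: `transporter_induced = control - TBOA` and
#' `antagonist_sensitive = TBOA - (TBOA + mGluR1/5 antagonist)`.
#'
#' @param control,tboa,tboa_ant A trace or list of sweep traces per
#'   condition, sharing the ramp protocol.
#' @param protocol List describing the command waveform: `ramp_start_ms`
#'   (time the down-ramp begins), `ramp_ms` (its duration, default 250),
#'   `v_from_mV` (voltage at ramp start, default -20), `v_to_mV` (voltage at
#'   ramp end, default -80), `grid_ms` (sampling grid, default 4).
#' @return A tibble of class `ramp_currents` with columns `time_ms`,
#'   `voltage_mV`, `current_control`, `current_tboa`, `current_tboa_ant`,
#'   `transporter_induced`, `antagonist_sensitive` (all pA).
#' @export
ramp_difference_currents <- function(control, tboa, tboa_ant,
                                     protocol = list()) {
  pr <- utils::modifyList(list(ramp_start_ms = 100, ramp_ms = 250,
                               v_from_mV = -20, v_to_mV = -80,
                               grid_ms = 4), protocol)
  avg <- function(x) {
    sweeps <- if (inherits(x, "ephys_trace")) list(x) else x
    lens <- vapply(sweeps, nrow, integer(1))
    if (length(unique(lens)) != 1L) {
      rlang::abort("sweeps within a condition differ in length.",
                   class = "synaptrain_error_protocol_mismatch")
    }
    ref <- sweeps[[1]]
    v <- rowMeans(do.call(cbind, lapply(sweeps, function(s) s$value)))
    list(time = ref$time_ms, value = v)
  }
  conds <- lapply(list(control = control, tboa = tboa,
                       tboa_ant = tboa_ant), avg)
  lens <- vapply(conds, function(c) length(c$time), integer(1))
  if (length(unique(lens)) != 1L ||
      any(vapply(conds, function(c) max(c$time), numeric(1)) <
          pr$ramp_start_ms + pr$ramp_ms)) {
    rlang::abort("conditions do not share the ramp protocol.",
                 class = "synaptrain_error_protocol_mismatch")
  }
  grid <- seq(pr$ramp_start_ms, pr$ramp_start_ms + pr$ramp_ms,
              by = pr$grid_ms)
  volt <- pr$v_from_mV + (pr$v_to_mV - pr$v_from_mV) *
    (grid - pr$ramp_start_ms) / pr$ramp_ms
  cur <- lapply(conds, function(c) {
    stats::approx(c$time, c$value, xout = grid)$y
  })
  out <- tibble::tibble(
    time_ms = grid,
    voltage_mV = volt,
    current_control = cur$control,
    current_tboa = cur$tboa,
    current_tboa_ant = cur$tboa_ant,
    transporter_induced = cur$control - cur$tboa,
    antagonist_sensitive = cur$tboa - cur$tboa_ant
  )
  structure(out, class = c("ramp_currents", class(out)), protocol = pr)
}

#' Plot a train decomposition
#'
#' @param object A [measure_train()] result.
#' @param ... Unused.
#' @return A ggplot of normalised phasic and tonic current against stimulus
#'   number (two panels).
#' @export
autoplot.train_decomposition <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[, c("stimulus", "phasic_pct", "tonic_pct")],
    cols = c("phasic_pct", "tonic_pct"),
    names_to = "component", values_to = "pct")
  df$component <- ifelse(df$component == "phasic_pct", "phasic", "tonic")
  ggplot2::ggplot(df, ggplot2::aes(.data$stimulus, .data$pct)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~component, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Stimulus number", y = "% of first peak")
}
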