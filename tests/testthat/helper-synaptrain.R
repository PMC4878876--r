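# Shared fixtures and small independent oracles used across tests.
# Everything here is deliberately plain-R arithmetic, independent of the
# package's own computation paths.

# Closed-form biexponential decay factor.
oracle_biexp <- function(t, tau_f, tau_s, ff) {
  ff * exp(-t / tau_f) + (1 - ff) * exp(-t / tau_s)
}

# Independently coded tonic recursion: T_n = (P_n + T_{n-1}) * D_n with
# constant single-exponential kinetics.
oracle_recursion_single <- function(P, tau, latency = 8.4) {
  D <- exp(-latency / tau)
  T_n <- numeric(length(P))
  prev <- 0
  for (i in seq_along(P)) {
    T_n[i] <- (P[i] + prev) * D
    prev <- T_n[i]
  }
  T_n
}

# Independently coded linear superposition with constant single-exponential
# kinetics.
oracle_superposition_single <- function(P, tau, isi = 10, latency = 8.4) {
  vapply(seq_along(P), function(n) {
    k <- seq_len(n)
    sum(P[k] * exp(-(latency + isi * (n - k)) / tau))
  }, numeric(1))
}

# A noiseless single-IPSC parameter set with wild-type-male first-IPSC
# kinetics (weighted tau 2.3 ms).
quiet_single_ipsc <- function(...) {
  args <- utils::modifyList(
    list(noise_sd_pA = 0, n_stimuli = 1, mglur_tonic_amplitude_pA = 0,
         tau_fast_last_ms = 1.5333, tau_slow_last_ms = 4.6),
    list(...))
  do.call(synth_ipsc_params, args)
}

# A flat voltage-clamp trace at a given level with fake stimulus times.
flat_trace <- function(level = 0, stim_times = 100 + 0:9 * 10,
                       duration = 350, dt = 0.02) {
  t <- seq(0, duration, by = dt)
  new_trace(t, rep(level, length(t)), mode = "voltage_clamp",
            stim_times_ms = stim_times)
}

# Build a current-clamp trace with spikes of a given waveform placed at
# known times (independent of the package generator).
manual_spike_trace <- function(spike_times, template = NULL,
                               baseline = -55, duration = 2000,
                               dt = 0.05) {
  template <- template %||% default_spike_template()
  t <- seq(0, duration, by = dt)
  v <- rep(baseline, length(t))
  for (ts in spike_times) {
    idx <- which(t >= ts + min(template$time_ms) &
                   t <= ts + max(template$time_ms))
    v[idx] <- v[idx] + approx(template$time_ms, template$delta_mV,
                              xout = t[idx] - ts, yleft = 0, yright = 0)$y
  }
  new_trace(t, v, mode = "current_clamp")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
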