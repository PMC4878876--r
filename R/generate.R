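# Synthetic voltage- and current-clamp trace generation with known ground
# truth. The IPSC event model: after a 0.6-ms synaptic delay the current
# rises along a saturating exponential to its peak at `peak_latency_ms`
# after stimulus onset, then decays as a double exponential referenced to
# the peak. Tonic ground truth is computed by exact linear superposition of
# these decays at the measurement points (8.4 ms after each peak).

# Unit-amplitude IPSC shape at elapsed time u (ms) since stimulus onset.
ipsc_unit_shape <- function(u, tau_fast, tau_slow, frac_fast,
                            rise_tau, delay, peak_latency) {
  out <- numeric(length(u))
  rise_dur <- peak_latency - delay
  rising <- u >= delay & u < peak_latency
  if (any(rising)) {
    if (rise_tau <= 0 || rise_dur <= 0) {
      out[rising] <- 1
    } else {
      out[rising] <- (1 - exp(-(u[rising] - delay) / rise_tau)) /
        (1 - exp(-rise_dur / rise_tau))
    }
  }
  decaying <- u >= peak_latency
  out[decaying] <- biexp_decay(u[decaying] - peak_latency,
                               tau_fast, tau_slow, frac_fast)
  out
}

# Continuous mGluR tonic level at time t: builds up with stimulus number as
# amp * (1 - exp(-(s - 1)/onset)), with s the (fractional) stimulus
# coordinate, clamped to the train.
mglur_level <- function(t, t1, isi, n_stimuli, amp, onset) {
  if (amp == 0) return(numeric(length(t)))
  s <- 1 + (t - t1) / isi
  s <- pmin(pmax(s, 1), n_stimuli + 1)
  amp * (1 - exp(-(s - 1) / onset))
}

#' Generate a synthetic evoked IPSC train trace
#'
#' Builds a voltage-clamp trace containing a baseline period followed by
#' `n_stimuli` IPSCs at `stim_freq_Hz`, with per-stimulus decay kinetics
#' interpolated linearly from the first- to the last-IPSC values, phasic
#' depression `P_n = P_1 (d + (1 - d) exp(-(n - 1)/k))`, an optional
#' stimulus-driven tonic inward (mGluR-like) current, and Gaussian noise.
#' Samples within the artifact blank after each stimulus are flagged.
#'
#' The returned trace carries ground truth: per-stimulus phasic amplitudes,
#' decay kinetics, the GABAergic tonic current at each measurement point
#' (computed by [exact_superposition_tonic()] on the generating parameters),
#' the mGluR level there, and the measurement times themselves
#' (`peak_latency_ms + 8.4` ms after each stimulus onset, i.e. the next
#' stimulus onset for a 100-Hz train with the default 1.6-ms peak latency).
#'
#' @param params A [synth_ipsc_params()] object.
#' @param seed Integer seed fixing all randomness.
#' @param duration_ms Optional total trace duration; must be long enough to
#'   contain the baseline, the train and the final measurement point.
#' @param meta Optional label list stored on the trace.
#' @return An [new_trace()] voltage-clamp trace with attribute
#'   `ground_truth`.
#' @export
#' @examples
#' p <- synth_ipsc_params(noise_sd_pA = 0, n_stimuli = 5)
#' tr <- generate_ipsc_train_trace(p, seed = 1)
#' trace_ground_truth(tr)$tonic_pA
generate_ipsc_train_trace <- function(params, seed, duration_ms = NULL,
                                      meta = list()) {
  stopifnot(inherits(params, "synth_ipsc_params"))
  p <- params
  isi <- 1000 / p$stim_freq_Hz
  latency <- 8.4
  stim_times <- p$pre_ms + (seq_len(p$n_stimuli) - 1) * isi
  t_meas <- stim_times + p$peak_latency_ms + latency
  needed <- max(t_meas) + p$post_ms
  if (is.null(duration_ms)) {
    duration_ms <- needed
  } else if (duration_ms < needed) {
    rlang::abort(
      sprintf("trace duration %.1f ms cannot contain a %d-stimulus train (needs %.1f ms).",
              duration_ms, p$n_stimuli, needed),
      class = "synaptrain_error_train_too_long")
  }
  if (p$sample_interval_ms <= 0) {
    rlang::abort("sample interval must be positive.",
                 class = "synaptrain_error_bad_params")
  }

  time_ms <- seq(0, duration_ms, by = p$sample_interval_ms)
  value <- rep(p$baseline_pA, length(time_ms))

  n <- seq_len(p$n_stimuli)
  w <- if (p$n_stimuli > 1) (n - 1) / (p$n_stimuli - 1) else rep(0, 1)
  tau_f <- (1 - w) * p$tau_fast_first_ms + w * p$tau_fast_last_ms
  tau_s <- (1 - w) * p$tau_slow_first_ms + w * p$tau_slow_last_ms
  ff <- (1 - w) * p$frac_fast_first + w * p$frac_fast_last
  d <- p$depression_plateau_frac
  P <- p$peak_amplitude_pA *
    (d + (1 - d) * exp(-(n - 1) / p$depression_rate_stimuli))

  for (i in n) {
    from <- findInterval(stim_times[i], time_ms)
    idx <- from:length(time_ms)
    u <- time_ms[idx] - stim_times[i]
    value[idx] <- value[idx] + P[i] *
      ipsc_unit_shape(u, tau_f[i], tau_s[i], ff[i], p$rise_tau_ms,
                      p$artifact_blank_ms, p$peak_latency_ms)
  }
  value <- value + mglur_level(time_ms, stim_times[1], isi, p$n_stimuli,
                               p$mglur_tonic_amplitude_pA,
                               p$mglur_onset_tau_stimuli)
  if (p$noise_sd_pA > 0) {
    value <- value + with_seed(seed, stats::rnorm(length(value),
                                                  sd = p$noise_sd_pA))
  }

  kin <- tibble::tibble(tau_fast_ms = tau_f, tau_slow_ms = tau_s,
                        frac_fast = ff)
  tonic_gaba <- exact_superposition_tonic(P, kin, isi_ms = isi,
                                          latency_ms = latency)
  mglur <- mglur_level(t_meas, stim_times[1], isi, p$n_stimuli,
                       p$mglur_tonic_amplitude_pA, p$mglur_onset_tau_stimuli)
  gt <- list(stimulus = n,
             phasic_pA = P,
             tau_fast_ms = tau_f, tau_slow_ms = tau_s, frac_fast = ff,
             tonic_gaba_pA = tonic_gaba,
             mglur_pA = mglur,
             tonic_pA = tonic_gaba + mglur,
             measurement_times_ms = t_meas,
             weighted_tau_first_ms = ff[1] * tau_f[1] + (1 - ff[1]) * tau_s[1],
             weighted_tau_last_ms = ff[p$n_stimuli] * tau_f[p$n_stimuli] +
               (1 - ff[p$n_stimuli]) * tau_s[p$n_stimuli],
             peak_latency_ms = p$peak_latency_ms,
             latency_ms = latency,
             baseline_pA = p$baseline_pA,
             seed = seed)

  new_trace(time_ms, value, mode = "voltage_clamp",
            stim_times_ms = stim_times,
            artifact_blank_ms = p$artifact_blank_ms,
            ground_truth = gt, meta = meta)
}

# Piecewise-constant firing-rate profile for a rebound protocol. Returns a
# tibble of segments (t0, t1, rate_Hz).
rate_profile <- function(p) {
  train_on <- p$settle_ms + p$pre_window_ms
  if (p$suppression_train_ms <= 0) {
    total <- p$settle_ms + p$pre_window_ms + p$tail_ms
    return(tibble::tibble(t0 = 0, t1 = total, rate_Hz = p$baseline_rate_Hz))
  }
  train_off <- train_on + p$suppression_train_ms
  reb_off <- train_off + p$rebound_duration_ms
  total <- train_off + max(p$post_window_ms, p$rebound_duration_ms) +
    p$tail_ms
  tibble::tibble(
    t0 = c(0, train_on, train_off, reb_off),
    t1 = c(train_on, train_off, reb_off, total),
    rate_Hz = c(p$baseline_rate_Hz, p$suppressed_rate_Hz,
                p$rebound_rate_Hz, p$baseline_rate_Hz)
  )
}

# Gamma-interval renewal process with a piecewise-constant rate, simulated
# by time-warping a unit-rate gamma renewal process through the cumulative
# intensity. Returns spike times in ms.
sample_renewal_spikes <- function(profile, shape) {
  dur_s <- (profile$t1 - profile$t0) / 1000
  lam <- cumsum(profile$rate_Hz * dur_s)
  lam0 <- c(0, lam[-length(lam)])
  total <- lam[length(lam)]
  if (total <= 0) return(numeric())
  n_max <- ceiling(total + 6 * sqrt(total / shape) + 10)
  s <- cumsum(stats::rgamma(n_max, shape = shape, rate = shape))
  while (s[length(s)] < total) {
    s <- c(s, s[length(s)] +
             cumsum(stats::rgamma(n_max, shape = shape, rate = shape)))
  }
  s <- s[s < total]
  seg <- findInterval(s, lam0)
  rate <- profile$rate_Hz[seg]
  t <- profile$t0[seg] + 1000 * (s - lam0[seg]) / rate
  t <- sort(t)
  # enforce a 2-ms minimum separation (waveforms must not fuse)
  if (length(t) > 1) {
    keep <- c(TRUE, diff(t) >= 2)
    t <- t[keep]
  }
  t
}

#' Generate a synthetic current-clamp spiking trace
#'
#' Spikes are placed by a gamma-interval renewal process at
#' `baseline_rate_Hz` before the inhibitory train, near-zero rate during it,
#' `rebound_rate_Hz` for `rebound_duration_ms` afterwards, then baseline
#' again; a spike waveform template is added at each spike time on top of a
#' noisy baseline potential. With `suppression_train_ms = 0` the trace is
#' purely spontaneous (no train).
#'
#' @param params A [synth_spiking_params()] object.
#' @param seed Integer seed fixing all randomness.
#' @param meta Optional label list stored on the trace.
#' @return A current-clamp [new_trace()] whose `ground_truth` holds the true
#'   spike (peak) times, the rate profile, and the train window.
#' @export
generate_spiking_trace <- function(params, seed, meta = list()) {
  stopifnot(inherits(params, "synth_spiking_params"))
  p <- params
  profile <- rate_profile(p)
  total <- max(profile$t1)
  if (p$suppression_train_ms > 0 &&
      (p$pre_window_ms > p$settle_ms + p$pre_window_ms ||
       p$suppression_train_ms + p$post_window_ms + p$settle_ms > total)) {
    rlang::abort("analysis windows do not fit in the trace.",
                 class = "synaptrain_error_window")
  }

  res <- with_seed(seed, {
    spikes <- sample_renewal_spikes(profile, p$isi_shape)
    time_ms <- seq(0, total, by = p$sample_interval_ms)
    value <- p$baseline_vm_mV +
      stats::rnorm(length(time_ms), sd = p$noise_sd_mV)
    list(spikes = spikes, time_ms = time_ms, value = value)
  })
  time_ms <- res$time_ms
  value <- res$value
  tpl <- p$spike_template
  for (ts in res$spikes) {
    lo <- findInterval(ts + min(tpl$time_ms), time_ms)
    hi <- min(findInterval(ts + max(tpl$time_ms), time_ms) + 1L,
              length(time_ms))
    idx <- max(lo, 1L):hi
    value[idx] <- value[idx] +
      stats::approx(tpl$time_ms, tpl$delta_mV, xout = time_ms[idx] - ts,
                    yleft = 0, yright = 0)$y
  }

  train_on <- if (p$suppression_train_ms > 0) p$settle_ms + p$pre_window_ms
              else NA_real_
  train_off <- if (!is.na(train_on)) train_on + p$suppression_train_ms
               else NA_real_
  stim_times <- if (!is.na(train_on)) {
    seq(train_on, train_off - 10, by = 10)
  } else numeric()

  gt <- list(spike_times_ms = res$spikes,
             rate_profile = profile,
             train_onset_ms = train_on,
             train_end_ms = train_off,
             pre_window_ms = p$pre_window_ms,
             post_window_ms = p$post_window_ms,
             baseline_vm_mV = p$baseline_vm_mV,
             seed = seed)
  new_trace(time_ms, value, mode = "current_clamp",
            stim_times_ms = stim_times, artifact_blank_ms = 0,
            ground_truth = gt, meta = meta)
}

# One lognormal multiplier with mean 1 and coefficient of variation cv.
lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sig2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -sig2 / 2, sd = sqrt(sig2)))
}

#' Generate a synthetic cohort of cells from group presets
#'
#' For each preset and cell, per-cell parameters are drawn with lognormal
#' multiplicative variability (mean 1, coefficient of variation `cv`) around
#' the preset means: one amplitude multiplier, one kinetic-speed multiplier
#' (applied jointly to all decay time constants, preserving their ordering),
#' one mGluR-amplitude multiplier, one spontaneous-rate multiplier and one
#' rebound-increment multiplier. Every cell receives traces in a control and
#' a drug condition; the drug condition removes the mGluR tonic component
#' from IPSC trains (CPCCOEt-like) and uses the preset's drug rebound rate.
#' Rebound protocols hold the pre-stimulus rate at 40 Hz, emulating the
#' experimental bias current.
#'
#' @param presets List of group presets as returned by [group_presets()].
#' @param n_cells_per_group Cells per group (>= 1).
#' @param seed Integer seed; fixed seed gives identical cohorts.
#' @param cv Per-cell lognormal coefficient of variation (default 0.3).
#' @param what Trace modalities to generate: any of `"ipsc"` (voltage-clamp
#'   trains), `"rebound"` (current-clamp rebound protocol), `"spontaneous"`
#'   (current-clamp, no train; control condition only).
#' @param conditions Drug conditions to generate for the ipsc and rebound
#'   modalities (default both `"control"` and `"drug"`).
#' @return A list with `cells` (a tibble of per-cell true parameters and
#'   labels) and `traces` (a tibble with one row per generated trace and a
#'   list-column `trace`).
#' @export
generate_cohort <- function(presets = group_presets(),
                            n_cells_per_group = 11,
                            seed = 1,
                            cv = 0.3,
                            what = c("ipsc", "rebound", "spontaneous"),
                            conditions = c("control", "drug")) {
  what <- match.arg(what, several.ok = TRUE,
                    choices = c("ipsc", "rebound", "spontaneous"))
  conditions <- match.arg(conditions, several.ok = TRUE,
                          choices = c("control", "drug"))
  if (n_cells_per_group < 1) {
    rlang::abort("n_cells_per_group must be >= 1.",
                 class = "synaptrain_error_bad_params")
  }
  n_groups <- length(presets)
  n_cells <- n_groups * n_cells_per_group
  seeds <- derive_seeds(seed, n_cells * 6L)
  seed_mat <- matrix(seeds, nrow = n_cells)

  cells <- list()
  traces <- list()
  cell_idx <- 0L
  for (g in presets) {
    for (i in seq_len(n_cells_per_group)) {
      cell_idx <- cell_idx + 1L
      id <- sprintf("%s_c%02d", g$name, i)
      mult <- with_seed(seed_mat[cell_idx, 1L], lognorm_mult(5, cv))
      ip <- g$ipsc
      ip$peak_amplitude_pA <- ip$peak_amplitude_pA * mult[1]
      for (f in c("tau_fast_first_ms", "tau_slow_first_ms",
                  "tau_fast_last_ms", "tau_slow_last_ms")) {
        ip[[f]] <- ip[[f]] * mult[2]
      }
      ip$mglur_tonic_amplitude_pA <- ip$mglur_tonic_amplitude_pA * mult[3]
      ip <- do.call(synth_ipsc_params, unclass(ip))

      sp <- g$spiking
      sp$baseline_rate_Hz <- sp$baseline_rate_Hz * mult[4]
      reb_pre <- 40
      sp$rebound_rate_Hz <- reb_pre +
        (g$spiking$rebound_rate_Hz - reb_pre) * mult[5]
      sp$rebound_rate_drug_Hz <- reb_pre +
        (g$spiking$rebound_rate_drug_Hz - reb_pre) * mult[5]

      meta0 <- list(cell_id = id, group = g$name, sex = g$sex,
                    genotype = g$genotype)
      cells[[cell_idx]] <- tibble::tibble(
        cell_id = id, group = g$name, sex = g$sex, genotype = g$genotype,
        peak_amplitude_pA = ip$peak_amplitude_pA,
        weighted_tau_first_ms = ip$frac_fast_first * ip$tau_fast_first_ms +
          (1 - ip$frac_fast_first) * ip$tau_slow_first_ms,
        weighted_tau_last_ms = ip$frac_fast_last * ip$tau_fast_last_ms +
          (1 - ip$frac_fast_last) * ip$tau_slow_last_ms,
        mglur_tonic_amplitude_pA = ip$mglur_tonic_amplitude_pA,
        baseline_rate_Hz = sp$baseline_rate_Hz,
        rebound_rate_Hz = sp$rebound_rate_Hz,
        rebound_rate_drug_Hz = sp$rebound_rate_drug_Hz,
        holding_current_pA = g$holding_current_pA)

      if ("ipsc" %in% what) {
        ip_drug <- unclass(ip)
        ip_drug$mglur_tonic_amplitude_pA <- 0
        ip_drug <- do.call(synth_ipsc_params, ip_drug)
        for (cond in conditions) {
          pp <- if (cond == "control") ip else ip_drug
          sd_i <- seed_mat[cell_idx, if (cond == "control") 2L else 3L]
          traces[[length(traces) + 1L]] <- tibble::tibble(
            cell_id = id, group = g$name, sex = g$sex,
            genotype = g$genotype, condition = cond, modality = "ipsc",
            trace = list(generate_ipsc_train_trace(
              pp, seed = sd_i, meta = c(meta0, list(condition = cond)))))
        }
      }
      if ("rebound" %in% what) {
        for (cond in conditions) {
          sp_c <- unclass(sp)
          sp_c$baseline_rate_Hz <- reb_pre
          if (cond == "drug") sp_c$rebound_rate_Hz <- sp$rebound_rate_drug_Hz
          sp_c <- do.call(synth_spiking_params, sp_c)
          sd_i <- seed_mat[cell_idx, if (cond == "control") 4L else 5L]
          traces[[length(traces) + 1L]] <- tibble::tibble(
            cell_id = id, group = g$name, sex = g$sex,
            genotype = g$genotype, condition = cond, modality = "rebound",
            trace = list(generate_spiking_trace(
              sp_c, seed = sd_i, meta = c(meta0, list(condition = cond)))))
        }
      }
      if ("spontaneous" %in% what) {
        sp_s <- unclass(sp)
        sp_s$suppression_train_ms <- 0
        sp_s$pre_window_ms <- 1000
        sp_s <- do.call(synth_spiking_params, sp_s)
        traces[[length(traces) + 1L]] <- tibble::tibble(
          cell_id = id, group = g$name, sex = g$sex,
          genotype = g$genotype, condition = "control",
          modality = "spontaneous",
          trace = list(generate_spiking_trace(
            sp_s, seed = seed_mat[cell_idx, 6L],
            meta = c(meta0, list(condition = "control")))))
      }
    }
  }
  list(cells = dplyr::bind_rows(cells),
       traces = dplyr::bind_rows(traces))
}
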