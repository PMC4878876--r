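#' IPSC train generator parameters
#'
#' Parameter set for [generate_ipsc_train_trace()]. The modelled event is an
#' outward (positive) GABA-A IPSC at a -40 mV holding potential: after a
#' synaptic delay equal to the artifact blank, the current rises along a
#' saturating exponential to its peak at `peak_latency_ms`, then decays as a
#' double exponential referenced to the peak. Across the train the decay
#' parameters drift linearly from the `*_first` to the `*_last` values,
#' per-stimulus peaks depress exponentially to a plateau, and an optional
#' inward (negative) mGluR-like tonic current builds up with stimulus number.
#'
#' @param peak_amplitude_pA First-IPSC peak amplitude above baseline
#'   (outward positive).
#' @param tau_fast_first_ms,tau_slow_first_ms,frac_fast_first Decay kinetics
#'   of the first IPSC: fast/slow time constants (ms) and fast fraction.
#' @param tau_fast_last_ms,tau_slow_last_ms,frac_fast_last Decay kinetics of
#'   the last IPSC in the train.
#' @param rise_tau_ms Rise time constant (ms); 0 gives an instantaneous rise.
#' @param peak_latency_ms Time from stimulus onset to the IPSC peak (ms);
#'   the decay clock starts here. Default 1.6 ms (0.6 ms delay + 1 ms rise),
#'   so that tonic measurements 8.4 ms after the peak fall at the next
#'   stimulus onset of a 100-Hz train.
#' @param depression_plateau_frac Steady-state phasic amplitude as a fraction
#'   of the first peak.
#' @param depression_rate_stimuli E-fold constant (in stimuli) of the
#'   approach to the depression plateau.
#' @param mglur_tonic_amplitude_pA Asymptotic amplitude of the stimulus-driven
#'   tonic inward current (<= 0; 0 disables it).
#' @param mglur_onset_tau_stimuli E-fold constant (in stimuli) of the mGluR
#'   current build-up.
#' @param noise_sd_pA Gaussian sample noise (pA).
#' @param artifact_blank_ms Post-stimulus artifact blanking window (ms).
#' @param n_stimuli Number of stimuli in the train.
#' @param stim_freq_Hz Stimulation frequency.
#' @param sample_interval_ms Sampling interval (ms); default 0.02 (50 kHz).
#' @param baseline_pA Baseline holding current added to the whole trace.
#' @param pre_ms,post_ms Baseline before the first stimulus and tail after
#'   the last tonic measurement point (ms).
#'
#' @return A validated list of class `synth_ipsc_params`.
#' @export
synth_ipsc_params <- function(peak_amplitude_pA = 400,
                              tau_fast_first_ms = 1.5333,
                              tau_slow_first_ms = 4.6,
                              frac_fast_first = 0.75,
                              tau_fast_last_ms = 2.9333,
                              tau_slow_last_ms = 8.8,
                              frac_fast_last = 0.75,
                              rise_tau_ms = 0.3,
                              peak_latency_ms = 1.6,
                              depression_plateau_frac = 0.55,
                              depression_rate_stimuli = 2,
                              mglur_tonic_amplitude_pA = 0,
                              mglur_onset_tau_stimuli = 3,
                              noise_sd_pA = 5,
                              artifact_blank_ms = 0.6,
                              n_stimuli = 20,
                              stim_freq_Hz = 100,
                              sample_interval_ms = 0.02,
                              baseline_pA = 0,
                              pre_ms = 100,
                              post_ms = 100) {
  p <- as.list(environment())
  taus <- c(p$tau_fast_first_ms, p$tau_slow_first_ms,
            p$tau_fast_last_ms, p$tau_slow_last_ms, p$rise_tau_ms)
  stopifnot_param(all(taus[1:4] > 0), "all decay time constants must be > 0")
  stopifnot_param(p$rise_tau_ms >= 0, "rise_tau_ms must be >= 0")
  stopifnot_param(p$frac_fast_first >= 0 && p$frac_fast_first <= 1 &&
                    p$frac_fast_last >= 0 && p$frac_fast_last <= 1,
                  "fast fractions must lie in [0, 1]")
  stopifnot_param(p$tau_fast_first_ms <= p$tau_slow_first_ms &&
                    p$tau_fast_last_ms <= p$tau_slow_last_ms,
                  "tau_fast must not exceed tau_slow")
  stopifnot_param(p$n_stimuli >= 1, "n_stimuli must be >= 1")
  stopifnot_param(p$sample_interval_ms > 0, "sample_interval_ms must be > 0")
  stopifnot_param(p$stim_freq_Hz > 0, "stim_freq_Hz must be > 0")
  stopifnot_param(p$depression_plateau_frac > 0 &&
                    p$depression_plateau_frac <= 1.5,
                  "depression_plateau_frac must lie in (0, 1.5]")
  stopifnot_param(p$mglur_tonic_amplitude_pA <= 0,
                  "mglur_tonic_amplitude_pA is an inward current (<= 0)")
  stopifnot_param(p$peak_latency_ms >= p$artifact_blank_ms,
                  "peak_latency_ms must be >= artifact_blank_ms")
  stopifnot_param(p$peak_latency_ms <= 1000 / p$stim_freq_Hz,
                  "the IPSC peak must precede the next stimulus")
  structure(p, class = "synth_ipsc_params")
}

#' Spiking trace generator parameters
#'
#' Parameter set for [generate_spiking_trace()]: a current-clamp trace with
#' regular spontaneous firing (gamma-interval renewal process), optionally
#' interrupted by an inhibitory stimulus train that suppresses firing and is
#' followed by a rebound period of elevated rate.
#'
#' @param baseline_rate_Hz Spontaneous firing rate before the train.
#' @param rate_cv Lognormal coefficient of variation applied to per-cell
#'   rates when cohorts are generated (not used within a single trace).
#' @param isi_shape Gamma shape of the inter-spike-interval distribution
#'   (larger = more regular; 20 gives an ISI CV of ~0.22, typical of
#'   regularly firing cerebellar-nucleus cells).
#' @param spike_template Data frame with columns `time_ms` and `delta_mV`
#'   giving the spike waveform as a deviation from baseline potential, with
#'   a single maximum at `time_ms = 0`. Default [default_spike_template()].
#' @param rebound_rate_Hz Firing rate during the rebound window (control
#'   condition).
#' @param rebound_rate_drug_Hz Rebound rate with group I mGluRs blocked
#'   (drug condition); used by [generate_cohort()].
#' @param rebound_duration_ms Duration of the rebound period after train end.
#' @param suppression_train_ms Duration of the 100-Hz inhibitory train
#'   (0 disables the train, giving a purely spontaneous trace).
#' @param suppressed_rate_Hz Firing rate during the train (near zero).
#' @param pre_window_ms,post_window_ms Analysis windows flanking the train.
#' @param noise_sd_mV Gaussian membrane noise (mV).
#' @param baseline_vm_mV Inter-spike baseline potential.
#' @param sample_interval_ms Sampling interval (ms); default 0.05 (20 kHz).
#' @param settle_ms Extra recording time before the pre window.
#' @param tail_ms Extra recording time after the post window.
#'
#' @return A validated list of class `synth_spiking_params`.
#' @export
synth_spiking_params <- function(baseline_rate_Hz = 65,
                                 rate_cv = 0.3,
                                 isi_shape = 20,
                                 spike_template = default_spike_template(),
                                 rebound_rate_Hz = 60,
                                 rebound_rate_drug_Hz = rebound_rate_Hz,
                                 rebound_duration_ms = 300,
                                 suppression_train_ms = 500,
                                 suppressed_rate_Hz = 0,
                                 pre_window_ms = 500,
                                 post_window_ms = 300,
                                 noise_sd_mV = 0.5,
                                 baseline_vm_mV = -55,
                                 sample_interval_ms = 0.05,
                                 settle_ms = 200,
                                 tail_ms = 100) {
  p <- as.list(environment())
  rates <- c(p$baseline_rate_Hz, p$rebound_rate_Hz, p$rebound_rate_drug_Hz,
             p$suppressed_rate_Hz)
  stopifnot_param(all(rates >= 0), "rates must be >= 0")
  stopifnot_param(p$pre_window_ms > 0 && p$post_window_ms > 0 &&
                    p$rebound_duration_ms > 0,
                  "windows must be > 0")
  stopifnot_param(p$suppression_train_ms >= 0,
                  "suppression_train_ms must be >= 0")
  stopifnot_param(p$isi_shape > 0, "isi_shape must be > 0")
  stopifnot_param(p$sample_interval_ms > 0, "sample_interval_ms must be > 0")
  tpl <- p$spike_template
  stopifnot_param(is.data.frame(tpl) &&
                    all(c("time_ms", "delta_mV") %in% names(tpl)),
                  "spike_template needs columns time_ms and delta_mV")
  stopifnot_param(sum(tpl$delta_mV == max(tpl$delta_mV)) == 1L,
                  "spike_template must have a single maximum")
  structure(p, class = "synth_spiking_params")
}

#' Default action-potential template
#'
#' A piecewise-linear spike waveform typical of fast-spiking CbN neurons:
#' linear rise to the peak, linear fall into an after-hyperpolarisation,
#' exponential recovery to baseline. The peak sits at `time_ms = 0`.
#'
#' @param rise_ms,fall_ms Rise (threshold to peak) and fall (peak to AHP)
#'   durations.
#' @param peak_delta_mV Peak height above baseline.
#' @param ahp_delta_mV AHP depth below baseline (positive number).
#' @param ahp_tau_ms Recovery time constant of the AHP.
#' @param dt_ms Template sampling interval.
#' @return A tibble with columns `time_ms` and `delta_mV`.
#' @export
default_spike_template <- function(rise_ms = 0.2, fall_ms = 0.3,
                                   peak_delta_mV = 60, ahp_delta_mV = 8,
                                   ahp_tau_ms = 1.2, dt_ms = 0.01) {
  t <- seq(-rise_ms, fall_ms + 5 * ahp_tau_ms, by = dt_ms)
  d <- numeric(length(t))
  rise <- t < 0
  d[rise] <- peak_delta_mV * (1 + t[rise] / rise_ms)
  fall <- t >= 0 & t <= fall_ms
  d[fall] <- peak_delta_mV - (peak_delta_mV + ahp_delta_mV) * t[fall] / fall_ms
  rec <- t > fall_ms
  d[rec] <- -ahp_delta_mV * exp(-(t[rec] - fall_ms) / ahp_tau_ms)
  tibble::tibble(time_ms = t, delta_mV = d)
}

stopifnot_param <- function(ok, msg) {
  if (!isTRUE(ok)) {
    rlang::abort(paste0("Invalid generator parameters: ", msg),
                 class = "synaptrain_error_bad_params")
  }
}

#' Sex-by-genotype group presets
#'
#' Returns the four group presets (wild-type and *Gabrb3* m-/p+, male and
#' female) used by [generate_cohort()]. Values are read from the YAML file
#' shipped in `inst/extdata/group_presets.yaml`; each preset carries IPSC
#' train parameters, spiking parameters, a holding current and a
#' TBOA-unmasked mGluR current, parameterised from published group means for
#' cerebellar-nucleus neurons (e.g. first-IPSC weighted tau 2.3 ms and
#' 65 spikes/s spontaneous rate for wild-type males, 1.8 ms and 98 spikes/s
#' for wild-type females).
#'
#' @param file Optional path to an alternative preset YAML file.
#' @return A named list of four presets, each a list with elements `name`,
#'   `sex`, `genotype`, `holding_current_pA`, `mglur_tboa_current_pA`,
#'   `ipsc` (a [synth_ipsc_params()] object) and `spiking`
#'   (a [synth_spiking_params()] object).
#' @export
#' @examples
#' names(group_presets())
group_presets <- function(file = NULL) {
  file <- file %||% system.file("extdata", "group_presets.yaml",
                                package = "synaptrain", mustWork = TRUE)
  raw <- yaml::read_yaml(file)
  presets <- purrr::map(raw, function(g) {
    list(name = g$name,
         sex = rlang::arg_match0(g$sex, c("male", "female")),
         genotype = rlang::arg_match0(g$genotype, c("+/+", "m-/p+")),
         holding_current_pA = g$holding_current_pA,
         mglur_tboa_current_pA = g$mglur_tboa_current_pA,
         ipsc = do.call(synth_ipsc_params, g$ipsc),
         spiking = do.call(synth_spiking_params, g$spiking))
  })
  stats::setNames(presets, purrr::map_chr(presets, "name"))
}
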