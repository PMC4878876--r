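test_that("noiseless traces equal the analytic superposition everywhere", {
  p <- synth_ipsc_params(noise_sd_pA = 0, n_stimuli = 8,
                         mglur_tonic_amplitude_pA = -20)
  tr <- generate_ipsc_train_trace(p, seed = 1)
  gt <- trace_ground_truth(tr)
  st <- trace_stim_times(tr)
  # independent reconstruction with plain arithmetic
  expected <- rep(0, nrow(tr))
  for (i in seq_along(st)) {
    u <- tr$time_ms - st[i]
    rise_dur <- p$peak_latency_ms - p$artifact_blank_ms
    shape <- numeric(length(u))
    rising <- u >= p$artifact_blank_ms & u < p$peak_latency_ms
    shape[rising] <- (1 - exp(-(u[rising] - p$artifact_blank_ms) / 0.3)) /
      (1 - exp(-rise_dur / 0.3))
    dec <- u >= p$peak_latency_ms
    shape[dec] <- oracle_biexp(u[dec] - p$peak_latency_ms,
                               gt$tau_fast_ms[i], gt$tau_slow_ms[i],
                               gt$frac_fast[i])
    expected <- expected + gt$phasic_pA[i] * shape
  }
  s <- pmin(pmax(1 + (tr$time_ms - st[1]) / 10, 1), length(st) + 1)
  expected <- expected +
    ifelse(tr$time_ms < st[1], 0, -20 * (1 - exp(-(s - 1) / 3)))
  expect_lt(max(abs(tr$value - expected)), 1e-9 * p$peak_amplitude_pA)
})

test_that("generator ground truth is internally consistent", {
  p <- synth_ipsc_params(noise_sd_pA = 0)
  tr <- generate_ipsc_train_trace(p, seed = 1)
  gt <- trace_ground_truth(tr)
  # first-IPSC weighted tau equals F_f tau_f + F_s tau_s exactly
  expect_identical(gt$weighted_tau_first_ms,
                   gt$frac_fast[1] * gt$tau_fast_ms[1] +
                     (1 - gt$frac_fast[1]) * gt$tau_slow_ms[1])
  # tonic ground truth is non-negative without an mGluR component
  expect_true(all(gt$tonic_gaba_pA >= 0))
  expect_identical(gt$tonic_pA, gt$tonic_gaba_pA + gt$mglur_pA)
})

test_that("with tau drift disabled, ground-truth tonic equals the exact-superposition oracle", {
  p <- synth_ipsc_params(noise_sd_pA = 0, n_stimuli = 20,
                         tau_fast_last_ms = 1.5333, tau_slow_last_ms = 4.6,
                         mglur_tonic_amplitude_pA = 0)
  tr <- generate_ipsc_train_trace(p, seed = 1)
  gt <- trace_ground_truth(tr)
  oracle <- exact_superposition_tonic(
    gt$phasic_pA,
    data.frame(tau_fast_ms = 1.5333, tau_slow_ms = 4.6, frac_fast = 0.75),
    isi_ms = 10, latency_ms = 8.4)
  expect_equal(gt$tonic_pA, oracle, tolerance = 1e-12)
  # and the trace itself reproduces it at the measurement points
  at <- vapply(gt$measurement_times_ms, function(tm) {
    tr$value[which.min(abs(tr$time_ms - tm))]
  }, numeric(1))
  expect_lt(max(abs(at - gt$tonic_pA)), 0.005 * p$peak_amplitude_pA)
})

test_that("fixed seeds give bit-identical traces and cohorts", {
  p <- synth_ipsc_params(n_stimuli = 5)
  expect_identical(generate_ipsc_train_trace(p, seed = 99),
                   generate_ipsc_train_trace(p, seed = 99))
  sp <- synth_spiking_params()
  expect_identical(generate_spiking_trace(sp, seed = 5),
                   generate_spiking_trace(sp, seed = 5))
  c1 <- generate_cohort(n_cells_per_group = 1, seed = 3, what = "ipsc")
  c2 <- generate_cohort(n_cells_per_group = 1, seed = 3, what = "ipsc")
  expect_identical(c1, c2)
})

test_that("generator rejects impossible geometries", {
  expect_error(synth_ipsc_params(sample_interval_ms = 0),
               class = "synaptrain_error_bad_params")
  expect_error(synth_ipsc_params(tau_fast_first_ms = 5,
                                 tau_slow_first_ms = 2),
               class = "synaptrain_error_bad_params")
  expect_error(synth_ipsc_params(depression_plateau_frac = 0),
               class = "synaptrain_error_bad_params")
  p <- synth_ipsc_params(n_stimuli = 20)
  expect_error(generate_ipsc_train_trace(p, seed = 1, duration_ms = 150),
               class = "synaptrain_error_train_too_long")
})

test_that("spiking generator places spikes at the configured rates", {
  sp <- synth_spiking_params(baseline_rate_Hz = 65,
                             suppression_train_ms = 0,
                             pre_window_ms = 1000)
  # Monte-Carlo over seeds: the realised rate is unbiased
  rates <- vapply(1:30, function(s) {
    gt <- trace_ground_truth(generate_spiking_trace(sp, seed = s))
    sum(gt$spike_times_ms >= 200 & gt$spike_times_ms < 1200)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 65), 2)  # < 2% bias contract at 1-s windows
  # rebound = baseline gives ~0 percent change on average
  sp0 <- synth_spiking_params(baseline_rate_Hz = 40, rebound_rate_Hz = 40)
  pc <- vapply(1:20, function(s) {
    rebound_percent_change(generate_spiking_trace(sp0, seed = s))$percent_change
  }, numeric(1))
  expect_lt(abs(mean(pc)), 5)
})

test_that("cohorts with zero variability reproduce preset means exactly", {
  coh <- generate_cohort(n_cells_per_group = 1, seed = 1, cv = 0,
                         what = "ipsc")
  pres <- group_presets()
  expect_equal(nrow(coh$cells), 4)
  for (g in names(pres)) {
    row <- coh$cells[coh$cells$group == g, ]
    expect_equal(row$peak_amplitude_pA, pres[[g]]$ipsc$peak_amplitude_pA)
    expect_equal(row$mglur_tonic_amplitude_pA,
                 pres[[g]]$ipsc$mglur_tonic_amplitude_pA)
    expect_equal(row$baseline_rate_Hz,
                 pres[[g]]$spiking$baseline_rate_Hz)
  }
  expect_error(generate_cohort(n_cells_per_group = 0),
               class = "synaptrain_error_bad_params")
})

test_that("drug-condition traces lack the mGluR tonic component", {
  coh <- generate_cohort(n_cells_per_group = 1, seed = 8, cv = 0,
                         what = "ipsc")
  fem <- coh$traces[coh$traces$group == "wt_female", ]
  gt_ctl <- trace_ground_truth(fem$trace[fem$condition == "control"][[1]])
  gt_drg <- trace_ground_truth(fem$trace[fem$condition == "drug"][[1]])
  expect_true(all(gt_ctl$mglur_pA < 0))
  expect_true(all(gt_drg$mglur_pA == 0))
  expect_equal(gt_ctl$tonic_gaba_pA, gt_drg$tonic_gaba_pA)
})
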