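test_that("a flat trace decomposes to all-zero phasic and tonic currents", {
  d <- measure_train(flat_trace(level = -300))
  expect_true(all(d$phasic_pA == 0))
  expect_true(all(d$tonic_pA == 0))
  expect_equal(attr(d, "baseline_pA"), -300)
})

test_that("a single noiseless IPSC yields the closed-form peak and tonic values", {
  p <- quiet_single_ipsc()
  tr <- generate_ipsc_train_trace(p, seed = 1)
  d <- measure_train(tr)
  expect_equal(d$phasic_pA[1], 400, tolerance = 1e-6)
  t1_expected <- 400 * oracle_biexp(8.4, 1.5333, 4.6, 0.75)
  expect_equal(d$tonic_pA[1], t1_expected, tolerance = 0.01)
  expect_equal(d$phasic_pct[1], 100)
})

test_that("noiseless 20-stimulus trains match generator ground truth", {
  p <- synth_ipsc_params(noise_sd_pA = 0)
  tr <- generate_ipsc_train_trace(p, seed = 1)
  gt <- trace_ground_truth(tr)
  d <- measure_train(tr)
  expect_lt(max(abs(d$tonic_pA - gt$tonic_pA)),
            0.005 * p$peak_amplitude_pA)
  # reconstruction: P_n + T_{n-1} equals the measured peak exactly
  expect_equal(d$phasic_pA + c(0, d$tonic_pA[-nrow(d)]), d$peak_pA,
               tolerance = 1e-12)
})

test_that("normalised outputs are invariant under trace rescaling", {
  p <- synth_ipsc_params(noise_sd_pA = 0, n_stimuli = 12)
  tr <- generate_ipsc_train_trace(p, seed = 1)
  tr_scaled <- tr
  tr_scaled$value <- tr$value * 3.7
  d1 <- measure_train(tr)
  d2 <- measure_train(tr_scaled)
  expect_equal(d1$phasic_pct, d2$phasic_pct, tolerance = 1e-9)
  expect_equal(d1$tonic_pct, d2$tonic_pct, tolerance = 1e-9)
})

test_that("mean tonic over stimuli 5-10 averages exactly six values", {
  p <- synth_ipsc_params(noise_sd_pA = 0)
  d <- measure_train(generate_ipsc_train_trace(p, seed = 1))
  d$tonic_pct <- rep(8, nrow(d))
  expect_equal(mean_tonic_5_10(d), 8)
  d$tonic_pct[5:10] <- 5:10
  expect_equal(mean_tonic_5_10(d), 7.5)
  expect_error(mean_tonic_5_10(d[1:9, ]),
               class = "synaptrain_error_too_few_stimuli")
})

test_that("the mGluR tonic difference recovers the injected component", {
  expect_equal(mglur_tonic_difference(c(5, 6, 7), c(5, 6, 7))$mean_diff, 0)
  base <- synth_ipsc_params(noise_sd_pA = 0,
                            mglur_tonic_amplitude_pA = -40)
  drugp <- synth_ipsc_params(noise_sd_pA = 0)
  ctl <- lapply(1:3, function(s) {
    measure_train(generate_ipsc_train_trace(base, seed = s))
  })
  drg <- lapply(1:3, function(s) {
    measure_train(generate_ipsc_train_trace(drugp, seed = s))
  })
  res <- mglur_tonic_difference(ctl, drg)
  # generator arithmetic: mGluR level at measurement n is
  # -40 (1 - exp(-n/3)); stimuli 5-10 average, as % of the 400-pA peak
  expected <- -mean(-40 * (1 - exp(-(5:10) / 3))) / 400 * 100
  expect_equal(res$mean_diff, expected, tolerance = 0.05)
  expect_error(mglur_tonic_difference(list(), drg),
               class = "synaptrain_error_empty_group")
})

test_that("holding-current statistics return mean and sample variance", {
  tr <- flat_trace(level = -300, stim_times = numeric())
  hs <- holding_current_stats(tr, c(50, 250))
  expect_equal(hs$mean_pA, -300)
  expect_equal(hs$variance_pA2, 0)
  # white noise: variance close to sigma^2 for >= 1e4 samples
  set.seed(7)
  t <- seq(0, 400, by = 0.02)
  trn <- new_trace(t, rnorm(length(t), mean = -300, sd = 10),
                   mode = "voltage_clamp")
  hsn <- holding_current_stats(trn, c(0, 400))
  expect_equal(hsn$variance_pA2, 100, tolerance = 0.1)
  # a TBOA-like standing current shifts the mean by its amplitude
  trn2 <- trn
  trn2$value <- trn$value - 297
  expect_equal(holding_current_stats(trn2, c(0, 400))$mean_pA - hsn$mean_pA,
               -297, tolerance = 1e-9)
  expect_error(holding_current_stats(tr, c(100, 100.05)),
               class = "synaptrain_error_window_too_short")
})

test_that("ramp difference currents recover injected conductances", {
  # synthetic ramp: hold, step, then ramp -20 -> -80 mV over 250 ms
  t <- seq(0, 400, by = 0.1)
  volt <- ifelse(t < 100, -20, ifelse(t <= 350, -20 - 60 * (t - 100) / 250,
                                      -80))
  leak <- function(g, e = 0) g * (volt - e)  # pA, linear in V
  ctl <- new_trace(t, leak(5), mode = "voltage_clamp")
  # TBOA adds a -2 pA/mV conductance blocked by the antagonist
  tboa <- new_trace(t, leak(5) + 2 * (volt + 20), mode = "voltage_clamp")
  ant <- new_trace(t, leak(5), mode = "voltage_clamp")
  rc <- ramp_difference_currents(ctl, tboa, ant,
                                 protocol = list(ramp_start_ms = 100))
  expect_equal(rc$voltage_mV[1], -20)
  expect_equal(unique(diff(rc$time_ms)), 4)  # 4-ms grid
  expect_true(all(rc$voltage_mV >= -80 & rc$voltage_mV <= -20))
  # antagonist-sensitive current recovers the -2 pA/mV slope within 2%
  slope <- coef(lm(antagonist_sensitive ~ voltage_mV, data = rc))[2]
  expect_equal(unname(slope), 2, tolerance = 0.02)
  # control == TBOA gives identically zero transporter-induced current
  rc0 <- ramp_difference_currents(ctl, ctl, ant,
                                  protocol = list(ramp_start_ms = 100))
  expect_true(all(rc0$transporter_induced == 0))
  # averaging three identical sweeps equals a single sweep
  rc3 <- ramp_difference_currents(list(ctl, ctl, ctl), tboa, ant,
                                  protocol = list(ramp_start_ms = 100))
  expect_equal(rc3$current_control, rc$current_control)
  # mismatched protocols are rejected
  short <- new_trace(seq(0, 200, by = 0.1), rep(0, 2001),
                     mode = "voltage_clamp")
  expect_error(ramp_difference_currents(ctl, short, ant,
                                        protocol = list(ramp_start_ms = 100)),
               class = "synaptrain_error_protocol_mismatch")
})

test_that("steady-state amplitude averages the last stimuli", {
  p <- synth_ipsc_params(noise_sd_pA = 0)
  d <- measure_train(generate_ipsc_train_trace(p, seed = 1))
  expect_equal(steady_state_amplitude(d),
               mean(d$phasic_pct[16:20]))
})
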