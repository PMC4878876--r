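test_that("weighted tau is the fraction-weighted mean of the time constants", {
  expect_equal(weighted_tau(list(tau_fast_ms = 2, tau_slow_ms = 7,
                                 frac_fast = 1)), 2)
  expect_equal(weighted_tau(list(tau_fast_ms = 2, tau_slow_ms = 4,
                                 frac_fast = 0.5)), 3)
  expect_equal(weighted_tau(list(tau_fast_ms = 1.8, tau_slow_ms = 6,
                                 frac_fast = 0.75)), 2.85)
  # invariant under exchanging the fast/slow labels
  expect_equal(weighted_tau(list(tau_fast_ms = 6, tau_slow_ms = 1.8,
                                 frac_fast = 0.25)), 2.85)
  # strictly increasing in tau_slow
  wt <- vapply(seq(3, 9, by = 0.5), function(ts) {
    weighted_tau(list(tau_fast_ms = 1.8, tau_slow_ms = ts,
                      frac_fast = 0.75))
  }, numeric(1))
  expect_true(all(diff(wt) > 0))
})

test_that("noiseless decays are recovered to 1e-4 relative accuracy", {
  p <- quiet_single_ipsc(tau_fast_first_ms = 1.8, tau_slow_first_ms = 6,
                         frac_fast_first = 0.75, tau_fast_last_ms = 1.8,
                         tau_slow_last_ms = 6, frac_fast_last = 0.75)
  tr <- generate_ipsc_train_trace(p, seed = 1)
  f <- fit_biexponential(tr)
  expect_lt(abs(f$tau_fast_ms - 1.8) / 1.8, 1e-4)
  expect_lt(abs(f$tau_slow_ms - 6) / 6, 1e-4)
  expect_lt(abs(f$frac_fast - 0.75) / 0.75, 1e-4)
  expect_lt(abs(f$amplitude_pA - 400) / 400, 1e-3)
  # residual RMSE tiny relative to amplitude for noiseless data
  expect_lt(f$fit_rmse_pA, 1e-6 * f$amplitude_pA)
  # invariants of the returned object
  expect_equal(f$frac_fast + f$frac_slow, 1, tolerance = 1e-9)
  expect_lte(f$tau_fast_ms, f$tau_slow_ms)
  expect_equal(f$weighted_tau_ms,
               f$frac_fast * f$tau_fast_ms + f$frac_slow * f$tau_slow_ms)
})

test_that("pure single exponentials collapse to the single-exponential branch", {
  p <- quiet_single_ipsc(tau_fast_first_ms = 2, tau_slow_first_ms = 2,
                         frac_fast_first = 0.5, tau_fast_last_ms = 2,
                         tau_slow_last_ms = 2, frac_fast_last = 0.5)
  f <- fit_biexponential(generate_ipsc_train_trace(p, seed = 1))
  expect_true(f$single_exponential)
  expect_equal(f$frac_fast, 1)
  expect_equal(f$weighted_tau_ms, 2, tolerance = 1e-3)
})

test_that("weighted tau is recovered within 5% (median) at study noise", {
  # reduced-size Monte-Carlo; the acceptance suite runs 200 seeds
  errs <- vapply(1:30, function(s) {
    tr <- generate_ipsc_train_trace(quiet_single_ipsc(noise_sd_pA = 5),
                                    seed = s)
    abs(weighted_tau(fit_biexponential(tr)) - 2.3) / 2.3
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("degenerate inputs raise classed errors", {
  tr <- flat_trace(level = 5)
  expect_error(fit_biexponential(tr, stim_time_ms = 100),
               class = "synaptrain_error_no_decay")
  p <- quiet_single_ipsc()
  tr2 <- generate_ipsc_train_trace(p, seed = 1)
  expect_error(fit_biexponential(tr2, decay_window_ms = c(101.9, 102.1)),
               class = "synaptrain_error_window_too_short")
  expect_error(fit_biexponential(tr2, stim_index = 5),
               class = "synaptrain_error_index")
})

test_that("baseline anchoring fixes the baseline without changing noiseless fits", {
  p <- quiet_single_ipsc(baseline_pA = -120)
  tr <- generate_ipsc_train_trace(p, seed = 1)
  f_free <- fit_biexponential(tr)
  f_fix <- fit_biexponential(tr, baseline_pA = -120)
  expect_equal(f_fix$baseline_pA, -120)
  expect_equal(f_free$tau_fast_ms, f_fix$tau_fast_ms, tolerance = 1e-5)
  expect_equal(f_free$weighted_tau_ms, f_fix$weighted_tau_ms,
               tolerance = 1e-5)
})

test_that("train kinetics fits recover the first and last decay of a train", {
  p <- synth_ipsc_params(noise_sd_pA = 0)
  tr <- generate_ipsc_train_trace(p, seed = 1)
  fits <- fit_train_kinetics(tr)
  gt <- trace_ground_truth(tr)
  expect_equal(weighted_tau(fits$first), gt$weighted_tau_first_ms,
               tolerance = 0.02)
  # the last fit rides on residual tonic current; modest bias tolerated
  expect_equal(weighted_tau(fits$last), gt$weighted_tau_last_ms,
               tolerance = 0.12)
  expect_true(weighted_tau(fits$last) > weighted_tau(fits$first))
})

test_that("tidy and glance summarise fits in broom style", {
  f <- fit_biexponential(generate_ipsc_train_trace(quiet_single_ipsc(),
                                                   seed = 1))
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("fast", "slow"))
  expect_equal(sum(td$amplitude_pA), f$amplitude_pA)
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("weighted_tau_ms", "fit_rmse_pA", "n_points")
                  %in% names(gl)))
})
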