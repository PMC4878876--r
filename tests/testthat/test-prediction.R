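first_fit <- list(tau_fast_ms = 1.5, tau_slow_ms = 4.6, frac_fast = 0.75)
last_fit <- list(tau_fast_ms = 2.9, tau_slow_ms = 8.8, frac_fast = 0.6)

test_that("kinetic interpolation endpoints and weights are as modelled", {
  k1 <- interpolate_kinetics(first_fit, last_fit, n = 1)
  expect_equal(k1$tau_fast_ms, first_fit$tau_fast_ms)
  expect_equal(k1$tau_slow_ms, first_fit$tau_slow_ms)
  expect_equal(k1$frac_fast, first_fit$frac_fast)
  # midpoint at n = 11 with /20 weights
  k11 <- interpolate_kinetics(first_fit, last_fit, n = 11)
  expect_equal(k11$tau_fast_ms, (1.5 + 2.9) / 2)
  expect_equal(k11$frac_fast, (0.75 + 0.6) / 2)
  # n = 20 as printed: 0.05 first + 0.95 last, never reaching the last fit
  k20 <- interpolate_kinetics(first_fit, last_fit, n = 20)
  expect_equal(k20$tau_fast_ms, 0.05 * 1.5 + 0.95 * 2.9)
  expect_gt(abs(k20$tau_fast_ms - last_fit$tau_fast_ms), 1e-6)
  # endpoint_exact reaches the last fit at n = N
  ke <- interpolate_kinetics(first_fit, last_fit, n = 20,
                             mode = "endpoint_exact")
  expect_equal(ke$tau_fast_ms, last_fit$tau_fast_ms)
  # fractions always sum to one
  kk <- interpolate_kinetics(first_fit, last_fit, n = 1:20)
  expect_equal(kk$frac_fast + kk$frac_slow, rep(1, 20))
  expect_error(interpolate_kinetics(first_fit, last_fit, n = 21),
               class = "synaptrain_error_index")
})

test_that("the strict as-printed tau_slow line is reproducible on request", {
  k <- interpolate_kinetics(first_fit, last_fit, n = 11,
                            strict_tau_slow = TRUE)
  expect_equal(k$tau_slow_ms, 0.5 * first_fit$tau_fast_ms + 0.5 * 8.8)
})

test_that("the recursion reproduces closed-form single-stimulus values", {
  # half-decay construction: tau such that exp(-8.4/tau) = 1/2
  tau_half <- 8.4 / log(2)
  f <- list(tau_fast_ms = tau_half, tau_slow_ms = tau_half, frac_fast = 1)
  expect_equal(predict_tonic(100, f, f)$tonic_pred, 50, tolerance = 1e-12)
})

test_that("the recursion approaches its analytic limits", {
  P <- c(100, 80, 60, 50, 40)
  f_inf <- list(tau_fast_ms = Inf, tau_slow_ms = Inf, frac_fast = 0.75)
  expect_equal(predict_tonic(P, f_inf, f_inf)$tonic_pred, cumsum(P),
               tolerance = 1e-9)
  f_0 <- list(tau_fast_ms = 1e-9, tau_slow_ms = 1e-9, frac_fast = 0.75)
  expect_true(all(predict_tonic(P, f_0, f_0)$tonic_pred < 1e-9))
})

test_that("the recursion matches an independently coded oracle", {
  f <- list(tau_fast_ms = 10, tau_slow_ms = 10, frac_fast = 1)
  got <- predict_tonic(c(100, 100, 100), f, f)$tonic_pred
  expect_equal(got, oracle_recursion_single(c(100, 100, 100), 10),
               tolerance = 1e-10)
  expect_equal(round(got, 2), c(43.17, 61.81, 69.85))
})

test_that("the superposition oracle matches direct evaluation and bounds the recursion", {
  kin <- data.frame(tau_fast_ms = 10, tau_slow_ms = 10, frac_fast = 1)
  got <- exact_superposition_tonic(c(100, 100, 100), kin, isi_ms = 10,
                                   latency_ms = 8.4)
  direct <- 100 * c(exp(-0.84),
                    exp(-0.84) + exp(-1.84),
                    exp(-0.84) + exp(-1.84) + exp(-2.84))
  expect_equal(got, direct, tolerance = 1e-12)
  expect_equal(round(got[3], 2), 64.9)
  # the 10-ms interval decays more than the recursion's 8.4-ms factor
  f <- list(tau_fast_ms = 10, tau_slow_ms = 10, frac_fast = 1)
  expect_lt(got[3], predict_tonic(c(100, 100, 100), f, f)$tonic_pred[3])
})

test_that("recursion and superposition coincide when isi equals the latency", {
  f <- list(tau_fast_ms = 10, tau_slow_ms = 10, frac_fast = 1)
  P <- rep(100, 20)
  rec <- predict_tonic(P, f, f)$tonic_pred
  sup <- exact_superposition_tonic(
    P, data.frame(tau_fast_ms = 10, tau_slow_ms = 10, frac_fast = 1),
    isi_ms = 8.4, latency_ms = 8.4)
  expect_lt(max(abs(rec - sup) / sup), 1e-10)
  # a single stimulus is identical for arbitrary biexponential kinetics
  for (s in 1:5) {
    set.seed(s)
    tf <- runif(1, 0.5, 5); ts <- tf + runif(1, 0, 10)
    ff <- runif(1)
    fit <- list(tau_fast_ms = tf, tau_slow_ms = ts, frac_fast = ff)
    expect_equal(
      predict_tonic(100, fit, fit)$tonic_pred,
      exact_superposition_tonic(100, data.frame(tau_fast_ms = tf,
                                                tau_slow_ms = ts,
                                                frac_fast = ff)),
      tolerance = 1e-12)
  }
})

test_that("predicted tonic is monotone in amplitudes and time constants, and linear", {
  P <- c(100, 90, 70, 60)
  base <- predict_tonic(P, first_fit, last_fit)$tonic_pred
  # raising any P_k raises all subsequent T_n
  for (k in seq_along(P)) {
    P2 <- P
    P2[k] <- P2[k] + 10
    up <- predict_tonic(P2, first_fit, last_fit)$tonic_pred
    expect_true(all(up[k:length(P)] > base[k:length(P)]))
    expect_equal(up[seq_len(k - 1)], base[seq_len(k - 1)])
  }
  # slower kinetics give more tonic current
  slower <- lapply(first_fit, function(x) x)
  slower$tau_slow_ms <- first_fit$tau_slow_ms * 1.5
  up <- predict_tonic(P, slower, last_fit)$tonic_pred
  expect_true(all(up >= base))
  # linearity in P
  expect_equal(predict_tonic(P * 3.2, first_fit, last_fit)$tonic_pred,
               base * 3.2, tolerance = 1e-12)
  # T_n >= 0 whenever all P >= 0
  expect_true(all(base >= 0))
})

test_that("non-finite phasic inputs are rejected", {
  expect_error(predict_tonic(c(100, NA), first_fit, last_fit),
               class = "synaptrain_error_nonfinite")
  expect_error(exact_superposition_tonic(numeric(),
                                         data.frame(tau_fast_ms = 1,
                                                    tau_slow_ms = 2,
                                                    frac_fast = 0.5)),
               class = "synaptrain_error_nonfinite")
})

test_that("the phasic-only recursion variant differs as documented", {
  f <- list(tau_fast_ms = 10, tau_slow_ms = 10, frac_fast = 1)
  P <- c(100, 100, 100)
  alt <- predict_tonic(P, f, f, recursion = "phasic_only")$tonic_pred
  # T_n = sum_k P_k D_k: no decay of the accumulated tonic
  expect_equal(alt, cumsum(P * exp(-0.84)), tolerance = 1e-12)
  expect_true(all(alt >= predict_tonic(P, f, f)$tonic_pred))
})
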