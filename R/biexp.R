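#' Fit a double-exponential decay to an IPSC
#'
#' Fits `baseline + A * (F_f exp(-t/tau_f) + (1 - F_f) exp(-t/tau_s))` to the
#' decay phase of an evoked IPSC by bounded Levenberg-Marquardt least squares
#' (via \pkg{minpack.lm}). Time is referenced to the detected peak, so the
#' reported amplitude and fractions describe the decay at its origin.
#'
#' Initialisation is standard peeling: a log-linear regression on the last
#' third of the window seeds the slow time constant, the slow component is
#' subtracted, and a second log-linear regression on the early residual seeds
#' the fast one. The optimiser restarts from three perturbed seeds before
#' declaring non-convergence. If the two fitted time constants agree within
#' 5% or either fraction falls below 0.02, the fit collapses to a single
#' exponential (reported with `frac_fast = 1` and equal time constants).
#'
#' @param trace A voltage-clamp [new_trace()] (outward-positive current).
#' @param stim_index Which stimulus of the trace's train to fit (default 1).
#' @param stim_time_ms Stimulus onset time; overrides `stim_index`.
#' @param decay_window_ms Optional absolute `c(start, end)` window (ms). By
#'   default the window runs from 0.2 ms after the detected peak to 20 ms
#'   after the peak, truncated at the next stimulus onset for within-train
#'   fits.
#' @param peak_search_end_ms Peak search ends this long after stimulus onset
#'   (default 3.5 ms; the search starts at the end of the artifact blank).
#' @param fit_span_ms Maximum window length after the peak (default 20 ms).
#' @param min_points Minimum samples required in the window (default 30).
#' @param baseline_pA Optional fixed baseline. By default the baseline is a
#'   free fit parameter; supplying the known quiescent level (e.g. the
#'   pre-stimulus mean) removes the baseline/slow-component trade-off that
#'   destabilises short-window fits at realistic noise.
#'
#' @return An object of class `biexp_fit`: a list with `baseline_pA`,
#'   `amplitude_pA`, `tau_fast_ms`, `tau_slow_ms`, `frac_fast`, `frac_slow`,
#'   `weighted_tau_ms`, `fit_rmse_pA`, `fit_window_ms`, `peak_time_ms`,
#'   `stim_time_ms`, `n_points` and `single_exponential`.
#' @export
#' @examples
#' p <- synth_ipsc_params(noise_sd_pA = 0, n_stimuli = 1)
#' fit <- fit_biexponential(generate_ipsc_train_trace(p, seed = 1))
#' weighted_tau(fit)
fit_biexponential <- function(trace, stim_index = 1L, stim_time_ms = NULL,
                              decay_window_ms = NULL,
                              peak_search_end_ms = 3.5,
                              fit_span_ms = 20,
                              min_points = 30L,
                              baseline_pA = NULL) {
  stim_times <- trace_stim_times(trace)
  if (is.null(stim_time_ms)) {
    if (length(stim_times) < stim_index) {
      rlang::abort("stimulus index not present in trace.",
                   class = "synaptrain_error_index")
    }
    stim_time_ms <- stim_times[stim_index]
  }
  blank <- attr(trace, "artifact_blank_ms") %||% 0
  ok <- !trace$artifact
  t <- trace$time_ms
  y <- trace$value

  # peak: maximum after the artifact blank, before peak_search_end
  sel_peak <- ok & t > stim_time_ms + blank &
    t <= stim_time_ms + peak_search_end_ms
  if (!any(sel_peak)) {
    rlang::abort("no unblanked samples in the peak search window.",
                 class = "synaptrain_error_window_too_short")
  }
  i_peak <- which(sel_peak)[which.max(y[sel_peak])]
  t_peak <- t[i_peak]

  if (is.null(decay_window_ms)) {
    w_end <- t_peak + fit_span_ms
    nxt <- stim_times[stim_times > stim_time_ms + 1e-9]
    if (length(nxt)) w_end <- min(w_end, min(nxt))
    decay_window_ms <- c(t_peak + 0.2, min(w_end, max(t)))
  }
  if (decay_window_ms[1] < t_peak) {
    rlang::abort("decay window must start at or after the peak.",
                 class = "synaptrain_error_window_too_short")
  }
  sel <- ok & t >= decay_window_ms[1] & t <= decay_window_ms[2]
  if (sum(sel) < min_points) {
    rlang::abort(sprintf("decay window holds %d samples; >= %d required.",
                         sum(sel), min_points),
                 class = "synaptrain_error_window_too_short")
  }
  tt <- t[sel] - t_peak
  yy <- y[sel]

  # signal must decay across the window
  k <- max(5L, floor(length(yy) / 4))
  if (mean(yy[seq_len(k)]) <= mean(yy[seq.int(length(yy) - k + 1, length(yy))])) {
    rlang::abort("signal does not decrease over the decay window.",
                 class = "synaptrain_error_no_decay")
  }

  fixed_b <- !is.null(baseline_pA)
  seeds <- biexp_seed(tt, yy, b_fixed = baseline_pA)
  fit <- NULL
  perturb <- list(c(1, 1), c(0.5, 2), c(2, 0.5), c(0.3, 3))
  for (pm in perturb) {
    st <- seeds
    st$tf <- min(max(st$tf * pm[1], 0.1), 100)
    st$ts <- min(max(st$ts * pm[2], st$tf), 100)
    cand <- try(suppressWarnings(
      if (fixed_b) {
        yb <- yy - baseline_pA
        minpack.lm::nlsLM(
          yb ~ A * (f * exp(-tt / tf) + (1 - f) * exp(-tt / ts)),
          start = list(A = st$A, f = st$f, tf = st$tf, ts = st$ts),
          lower = c(A = 1e-12, f = 0, tf = 0.1, ts = 0.1),
          upper = c(A = Inf, f = 1, tf = 100, ts = 100),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          yy ~ b + A * (f * exp(-tt / tf) + (1 - f) * exp(-tt / ts)),
          start = list(b = st$b, A = st$A, f = st$f, tf = st$tf,
                       ts = st$ts),
          lower = c(b = -Inf, A = 1e-12, f = 0, tf = 0.1, ts = 0.1),
          upper = c(b = Inf, A = Inf, f = 1, tf = 100, ts = 100),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }), silent = TRUE)
    if (!inherits(cand, "try-error")) {
      if (is.null(fit) ||
          sum(stats::resid(cand)^2) < sum(stats::resid(fit)^2)) {
        fit <- cand
      }
    }
  }
  fit_single <- function(tau0, b0, A0) {
    try(suppressWarnings(
      if (fixed_b) {
        yb <- yy - baseline_pA
        minpack.lm::nlsLM(
          yb ~ A * exp(-tt / tau),
          start = list(A = A0, tau = max(min(tau0, 100), 0.1)),
          lower = c(A = 1e-12, tau = 0.1),
          upper = c(A = Inf, tau = 100),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      } else {
        minpack.lm::nlsLM(
          yy ~ b + A * exp(-tt / tau),
          start = list(b = b0, A = A0, tau = max(min(tau0, 100), 0.1)),
          lower = c(b = -Inf, A = 1e-12, tau = 0.1),
          upper = c(b = Inf, A = Inf, tau = 100),
          control = minpack.lm::nls.lm.control(maxiter = 300))
      }), silent = TRUE)
  }
  single <- FALSE
  if (is.null(fit)) {
    # the biexponential model is singular for genuinely single-exponential
    # decays; fall back to the one-component model before giving up
    sfit <- fit_single(seeds$ts, seeds$b, seeds$A)
    if (inherits(sfit, "try-error")) {
      rlang::abort("biexponential fit failed to converge after restarts.",
                   class = "synaptrain_error_nonconvergence")
    }
    sc <- as.list(stats::coef(sfit))
    cf <- list(b = if (fixed_b) baseline_pA else sc$b, A = sc$A, f = 1,
               tf = sc$tau, ts = sc$tau)
    fit <- sfit
    single <- TRUE
  } else {
    cf <- as.list(stats::coef(fit))
    if (fixed_b) cf$b <- baseline_pA
    if (cf$tf > cf$ts) {
      cf <- list(b = cf$b, A = cf$A, f = 1 - cf$f, tf = cf$ts, ts = cf$tf)
    }
    if ((cf$ts - cf$tf) / cf$ts < 0.05 || cf$f < 0.02 || cf$f > 0.98) {
      tau0 <- if (cf$f >= 0.5) cf$tf else cf$ts
      sfit <- fit_single(tau0, cf$b, cf$A)
      if (!inherits(sfit, "try-error")) {
        sc <- as.list(stats::coef(sfit))
        cf <- list(b = if (fixed_b) baseline_pA else sc$b, A = sc$A, f = 1,
                   tf = sc$tau, ts = sc$tau)
        fit <- sfit
        single <- TRUE
      }
    }
  }
  if (cf$A <= 0) {
    rlang::abort("fitted amplitude is not positive.",
                 class = "synaptrain_error_nonconvergence")
  }
  rmse <- sqrt(mean(stats::resid(fit)^2))
  structure(list(
    baseline_pA = cf$b,
    amplitude_pA = cf$A,
    tau_fast_ms = cf$tf,
    tau_slow_ms = cf$ts,
    frac_fast = cf$f,
    frac_slow = 1 - cf$f,
    weighted_tau_ms = cf$f * cf$tf + (1 - cf$f) * cf$ts,
    fit_rmse_pA = rmse,
    fit_window_ms = decay_window_ms,
    peak_time_ms = t_peak,
    stim_time_ms = stim_time_ms,
    n_points = length(yy),
    single_exponential = single
  ), class = "biexp_fit")
}

# Peeling initialisation for the biexponential fit.
biexp_seed <- function(tt, yy, b_fixed = NULL) {
  n <- length(yy)
  tail_idx <- seq.int(ceiling(2 * n / 3), n)
  b0 <- b_fixed %||% min(yy)
  z <- yy - b0 + 1e-9
  zt <- z[tail_idx]
  pos <- zt > max(z) / 1e4
  ts0 <- 10
  As0 <- max(z) / 4
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(zt[pos]) ~ tt[tail_idx][pos])
    sl <- stats::coef(lf)[2]
    if (is.finite(sl) && sl < 0) {
      ts0 <- min(max(-1 / sl, 0.1), 100)
      As0 <- exp(stats::coef(lf)[1])
    }
  }
  resid_fast <- z - As0 * exp(-tt / ts0)
  early <- seq_len(ceiling(n / 3))
  pos <- resid_fast[early] > max(z) / 1e4
  tf0 <- ts0 / 3
  Af0 <- max(resid_fast[1], max(z) / 4)
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(resid_fast[early][pos]) ~ tt[early][pos])
    sl <- stats::coef(lf)[2]
    if (is.finite(sl) && sl < 0) tf0 <- min(max(-1 / sl, 0.1), 100)
  }
  A0 <- Af0 + As0
  list(b = b0, A = max(A0, 1e-6), f = min(max(Af0 / max(A0, 1e-12), 0.05),
                                          0.95),
       tf = min(tf0, ts0), ts = max(tf0, ts0))
}

#' Fit first- and last-IPSC kinetics of a train
#'
#' Convenience wrapper used by the tonic-prediction pipeline: fits the decay
#' of the first and of the last IPSC of a train with baseline-constrained
#' biexponentials. The first fit is anchored to the pre-stimulus baseline
#' (mean over `baseline_window_ms` before the train); the last fit to the
#' post-train quiescent level (median over a window starting
#' `post_quiet_from_ms` after the last stimulus), where the GABAergic
#' residual has decayed but any standing (e.g. mGluR) current persists.
#' Anchoring removes the baseline/slow-component degeneracy of free fits in
#' the 10-ms inter-stimulus window.
#'
#' @param trace A voltage-clamp train [new_trace()].
#' @param baseline_window_ms Pre-train baseline window (default 50 ms).
#' @param post_quiet_from_ms,post_quiet_to_ms Post-train quiescence window
#'   relative to the last stimulus onset (defaults 60-90 ms).
#' @param ... Passed to [fit_biexponential()].
#' @return A list with elements `first` and `last`, each a `biexp_fit`.
#' @export
fit_train_kinetics <- function(trace, baseline_window_ms = 50,
                               post_quiet_from_ms = 60,
                               post_quiet_to_ms = 90, ...) {
  st <- trace_stim_times(trace)
  if (length(st) < 2) {
    rlang::abort("fit_train_kinetics needs a train of >= 2 stimuli.",
                 class = "synaptrain_error_bad_params")
  }
  t <- trace$time_ms
  pre <- trace$value[t >= st[1] - baseline_window_ms & t < st[1]]
  b_first <- mean(pre)
  t_last <- st[length(st)]
  qsel <- !trace$artifact & t >= t_last + post_quiet_from_ms &
    t <= min(t_last + post_quiet_to_ms, max(t))
  b_last <- if (sum(qsel) >= 10) stats::median(trace$value[qsel]) else NULL
  list(
    first = fit_biexponential(trace, stim_index = 1L,
                              baseline_pA = b_first, ...),
    last = fit_biexponential(trace, stim_index = length(st),
                             baseline_pA = b_last, ...)
  )
}

#' Amplitude-weighted decay time constant
#'
#' `F_fast * tau_fast + F_slow * tau_slow`: the decay time constants weighted
#' by the fractional contribution of each component to the total amplitude.
#'
#' @param fit A [fit_biexponential()] object, or any list with elements
#'   `tau_fast_ms`, `tau_slow_ms`, `frac_fast`.
#' @return Weighted decay time constant in ms.
#' @export
#' @examples
#' weighted_tau(list(tau_fast_ms = 1.8, tau_slow_ms = 6, frac_fast = 0.75))
weighted_tau <- function(fit) {
  fit$frac_fast * fit$tau_fast_ms + (1 - fit$frac_fast) * fit$tau_slow_ms
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<biexp_fit> A = %.4g pA, tau_f = %.4g ms (F_f = %.3f), ",
           "tau_s = %.4g ms, weighted tau = %.4g ms%s\n"),
    x$amplitude_pA, x$tau_fast_ms, x$frac_fast, x$tau_slow_ms,
    x$weighted_tau_ms,
    if (x$single_exponential) " [single exponential]" else ""))
  invisible(x)
}

#' Tidy a biexponential fit
#'
#' @param x A `biexp_fit` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per decay component (term,
#'   tau_ms, fraction, amplitude_pA). `glance()`: a one-row fit summary.
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("fast", "slow"),
    tau_ms = c(x$tau_fast_ms, x$tau_slow_ms),
    fraction = c(x$frac_fast, x$frac_slow),
    amplitude_pA = x$amplitude_pA * c(x$frac_fast, x$frac_slow)
  )
}

#' @rdname tidy.biexp_fit
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(
    amplitude_pA = x$amplitude_pA,
    baseline_pA = x$baseline_pA,
    weighted_tau_ms = x$weighted_tau_ms,
    fit_rmse_pA = x$fit_rmse_pA,
    n_points = x$n_points,
    window_start_ms = x$fit_window_ms[1],
    window_end_ms = x$fit_window_ms[2],
    single_exponential = x$single_exponential
  )
}
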