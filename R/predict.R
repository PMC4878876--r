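#' Interpolate IPSC decay kinetics across a stimulus train
#'
#' During 100-Hz trains the IPSC decay slows from the first to the last
#' stimulus. The tonic-prediction model captures this by interpolating the
#' fitted decay parameters of the first and last IPSCs linearly in stimulus
#' number. Two weighting modes are offered:
#'
#' * `"as_printed"`: weights `(n - 1) / 20` for each of tau_fast, tau_slow,
#'   F_fast and F_slow, regardless of the actual train length; at `n = 20`
#'   this reaches `0.05 x_first + 0.95 x_last` (it never attains the
#'   last-IPSC value). This is the model's original formulation, kept as the
#'   default for fidelity.
#' * `"endpoint_exact"`: weights `(n - 1) / (N - 1)`, so stimulus `N` gets
#'   exactly the last-IPSC parameters. Offered for sensitivity analysis.
#'
#' `F_slow` is always recomputed as `1 - F_fast` after interpolation. The
#' original printed equations interpolate tau_slow starting from the *fast*
#' time constant of the first IPSC, which is dimensionally inconsistent and
#' treated here as a typographical slip; set `strict_tau_slow = TRUE` to
#' reproduce it verbatim.
#'
#' @param first,last Biexponential fits of the first and last IPSCs
#'   ([fit_biexponential()] objects), or plain lists with elements
#'   `tau_fast_ms`, `tau_slow_ms`, `frac_fast`.
#' @param n Stimulus indices (vectorised), `1 <= n <= N`.
#' @param N Train length used for `endpoint_exact` weights (default 20).
#' @param mode Interpolation mode, see above.
#' @param strict_tau_slow Reproduce the printed tau_slow line verbatim.
#'
#' @return A tibble with columns `stimulus`, `tau_fast_ms`, `tau_slow_ms`,
#'   `frac_fast`, `frac_slow`.
#' @export
#' @examples
#' f <- list(tau_fast_ms = 1.5, tau_slow_ms = 4.6, frac_fast = 0.75)
#' l <- list(tau_fast_ms = 2.9, tau_slow_ms = 8.8, frac_fast = 0.75)
#' interpolate_kinetics(f, l, n = c(1, 11, 20))
interpolate_kinetics <- function(first, last, n, N = 20,
                                 mode = c("as_printed", "endpoint_exact"),
                                 strict_tau_slow = FALSE) {
  mode <- rlang::arg_match(mode)
  if (any(n < 1 | n > N)) {
    rlang::abort("stimulus index `n` must lie in [1, N].",
                 class = "synaptrain_error_index")
  }
  w <- if (mode == "as_printed") (n - 1) / 20 else (n - 1) / (N - 1)
  # a == b is short-circuited so that infinite limits interpolate cleanly
  lerp <- function(a, b) {
    if (a == b) rep(a, length(w)) else (1 - w) * a + w * b
  }
  tau_slow_from <- if (strict_tau_slow) first$tau_fast_ms else first$tau_slow_ms
  ff <- lerp(first$frac_fast, last$frac_fast)
  tibble::tibble(
    stimulus = as.integer(n),
    tau_fast_ms = lerp(first$tau_fast_ms, last$tau_fast_ms),
    tau_slow_ms = lerp(tau_slow_from, last$tau_slow_ms),
    frac_fast = ff,
    frac_slow = 1 - ff
  )
}

#' Predict the tonic current of an IPSC train from first/last-IPSC kinetics
#'
#' Implements the recursive tonic-current model: with per-stimulus decay
#' factor `D_n = F_fn exp(-L/tau_fn) + F_sn exp(-L/tau_sn)` evaluated at the
#' measurement latency `L = 8.4` ms (the interval between the IPSC peak and
#' the tonic read-out point of a 100-Hz train),
#'
#'     T_n = (P_n + T_{n-1}) * D_n,   T_0 = 0,
#'
#' where `P_n` is the measured phasic current of stimulus `n`. The recursion
#' treats the whole current present at the peak as decaying with the
#' interpolated kinetics of stimulus `n`; [exact_superposition_tonic()]
#' provides the assumption-free linear-superposition alternative for
#' quantifying this approximation. A variant that decays only the phasic
#' component (`recursion = "phasic_only"`, giving `T_n = P_n D_n + T_{n-1}`)
#' is exposed for comparison with alternative readings of the model.
#'
#' @param P Numeric vector of phasic amplitudes (pA, or % of the first peak).
#' @param first,last First- and last-IPSC fits (see [interpolate_kinetics()]).
#' @param mode,strict_tau_slow Passed to [interpolate_kinetics()].
#' @param latency_ms Evaluation latency of the decay factor (default 8.4).
#' @param recursion `"sum"` (default, as modelled) or `"phasic_only"`.
#' @param N Train length for interpolation weights; defaults to `length(P)`.
#'
#' @return A tibble of class `tonic_prediction` with columns `stimulus`,
#'   `phasic`, `tau_fast_ms`, `tau_slow_ms`, `frac_fast`, `frac_slow`,
#'   `decay_factor` and `tonic_pred`, in the units of `P`.
#' @export
#' @examples
#' single <- list(tau_fast_ms = 10, tau_slow_ms = 10, frac_fast = 1)
#' predict_tonic(c(100, 100, 100), single, single)$tonic_pred
predict_tonic <- function(P, first, last,
                          mode = c("as_printed", "endpoint_exact"),
                          latency_ms = 8.4,
                          recursion = c("sum", "phasic_only"),
                          strict_tau_slow = FALSE,
                          N = length(P)) {
  mode <- rlang::arg_match(mode)
  recursion <- rlang::arg_match(recursion)
  if (length(P) < 1 || !all(is.finite(P))) {
    rlang::abort("`P` must be non-empty and finite.",
                 class = "synaptrain_error_nonfinite")
  }
  kin <- interpolate_kinetics(first, last, seq_along(P), N = N, mode = mode,
                              strict_tau_slow = strict_tau_slow)
  D <- biexp_decay(latency_ms, kin$tau_fast_ms, kin$tau_slow_ms,
                   kin$frac_fast)
  T_pred <- numeric(length(P))
  prev <- 0
  for (i in seq_along(P)) {
    T_pred[i] <- if (recursion == "sum") (P[i] + prev) * D[i]
                 else P[i] * D[i] + prev
    prev <- T_pred[i]
  }
  out <- tibble::tibble(stimulus = kin$stimulus, phasic = as.numeric(P),
                        tau_fast_ms = kin$tau_fast_ms,
                        tau_slow_ms = kin$tau_slow_ms,
                        frac_fast = kin$frac_fast,
                        frac_slow = kin$frac_slow,
                        decay_factor = D,
                        tonic_pred = T_pred)
  structure(out, class = c("tonic_prediction", class(out)),
            latency_ms = latency_ms, mode = mode, recursion = recursion)
}

#' Exact linear-superposition tonic current
#'
#' The assumption-free oracle against which the recursive model is compared:
#' every stimulus contributes an independent biexponential decay, and the
#' tonic current at the measurement point of stimulus `n` is the plain sum
#' of all preceding decays evaluated at their respective elapsed times,
#'
#'     T_n = sum_{k <= n} P_k * D_k(latency + isi * (n - k)),
#'
#' where `D_k(t)` is stimulus `k`'s biexponential decay factor at elapsed
#' time `t` from its peak. For constant single-exponential kinetics with
#' `isi == latency` this coincides exactly with the recursion of
#' [predict_tonic()].
#'
#' @param P Phasic amplitudes per stimulus.
#' @param kinetics Data frame with columns `tau_fast_ms`, `tau_slow_ms`,
#'   `frac_fast`: one row per stimulus, or a single row recycled.
#' @param isi_ms Inter-stimulus interval (default 10, i.e. 100 Hz).
#' @param latency_ms Measurement latency after each peak (default 8.4).
#'
#' @return Numeric vector `T_n`, same length and units as `P`.
#' @export
exact_superposition_tonic <- function(P, kinetics, isi_ms = 10,
                                      latency_ms = 8.4) {
  if (length(P) < 1 || !all(is.finite(P))) {
    rlang::abort("`P` must be non-empty and finite.",
                 class = "synaptrain_error_nonfinite")
  }
  kinetics <- tibble::as_tibble(kinetics)
  if (nrow(kinetics) == 1L) {
    kinetics <- kinetics[rep(1L, length(P)), ]
  }
  if (nrow(kinetics) != length(P)) {
    rlang::abort("`kinetics` must have one row, or one row per stimulus.",
                 class = "synaptrain_error_bad_params")
  }
  n <- length(P)
  vapply(seq_len(n), function(i) {
    k <- seq_len(i)
    elapsed <- latency_ms + isi_ms * (i - k)
    sum(P[k] * biexp_decay(elapsed, kinetics$tau_fast_ms[k],
                           kinetics$tau_slow_ms[k], kinetics$frac_fast[k]))
  }, numeric(1))
}

#' @export
print.tonic_prediction <- function(x, ...) {
  cat(sprintf("<tonic_prediction> %d stimuli, mode = %s, latency = %g ms\n",
              nrow(x), attr(x, "mode"), attr(x, "latency_ms")))
  NextMethod()
}

#' Plot predicted (and, if supplied, measured) tonic current
#'
#' @param object A [predict_tonic()] result.
#' @param measured Optional numeric vector of measured tonic values (same
#'   units) to overlay.
#' @param ... Unused.
#' @return A ggplot of tonic current against stimulus number.
#' @export
autoplot.tonic_prediction <- function(object, measured = NULL, ...) {
  df <- tibble::tibble(stimulus = object$stimulus,
                       value = object$tonic_pred,
                       which = "predicted")
  if (!is.null(measured)) {
    df <- dplyr::bind_rows(df, tibble::tibble(stimulus = object$stimulus,
                                              value = measured,
                                              which = "measured"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$stimulus, .data$value,
                                   colour = .data$which,
                                   shape = .data$which)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Stimulus number", y = "Tonic current",
                  colour = NULL, shape = NULL)
}
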