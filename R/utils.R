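#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite number.",
                 class = "synaptrain_error_bad_seed")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive `n` child seeds from a base seed, all below 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Biexponential decay factor at elapsed time t (ms): F_f e^(-t/tau_f) +
# (1 - F_f) e^(-t/tau_s). Vectorised over t. tau = Inf and tau = 0 give the
# natural limits (1 and 0 for t > 0).
biexp_decay <- function(t, tau_fast, tau_slow, frac_fast) {
  n <- max(length(t), length(tau_fast), length(tau_slow), length(frac_fast))
  t <- rep_len(t, n)
  tau_fast <- rep_len(tau_fast, n)
  tau_slow <- rep_len(tau_slow, n)
  frac_fast <- rep_len(frac_fast, n)
  ef <- ifelse(tau_fast == 0, as.numeric(t <= 0), exp(-t / tau_fast))
  es <- ifelse(tau_slow == 0, as.numeric(t <= 0), exp(-t / tau_slow))
  frac_fast * ef + (1 - frac_fast) * es
}

# Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))
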