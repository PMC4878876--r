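---
title: "Phasic/tonic decomposition and tonic-current prediction in CbN neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic/tonic decomposition and tonic-current prediction in CbN neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptrain)
```

## The measurement problem

Cerebellar-nucleus (CbN) neurons are inhibited by convergent Purkinje-cell
input. Under voltage clamp at −40 mV, a 100-Hz, 200-ms stimulus train evokes
outward GABA-A IPSCs that do not decay fully in the 10-ms inter-stimulus
interval: each stimulus adds a *phasic* increment on top of the *tonic*
residue of all previous responses. The tonic component matters functionally
(it is what suppresses intrinsic firing), and its size depends both on IPSC
decay kinetics and on any standing inward current co-activated by the train
(in CbN cells, a group I mGluR current unmasked by glutamate spillover).
Separating those two contributions is the core of this package: measure the
tonic current, predict the part explained by GABAergic kinetics alone, and
attribute the difference.

## Decomposition geometry

All train measurements are baseline-subtracted (baseline = mean current over
the 50 ms before the first stimulus; the window length is a package default,
not a reported value). For stimulus $n$ at onset $t_n$:

* **Peak**: maximum over $(t_n + 0.6\,\mathrm{ms},\ t_n + 3.5\,\mathrm{ms}]$,
  excluding artifact-blanked samples (0.6 ms after each stimulus). The
  3.5-ms cut-off reflects that the IPSC rise completes within ~1.6 ms.
* **Tonic** $T_n$: the current 8.4 ms *after the IPSC peak*. The stimulus
  artifact and rise together occupy 1.6 ms, so the measurement lands
  10 ms after the stimulus onset — the onset of the next stimulus in a
  100-Hz train. The 8.4-ms figure is thus "the inter-stimulus interval less
  artifact and rise time". A median over ±0.2 ms (artifact samples
  excluded) suppresses single-sample noise; the underlying definition is a
  point measurement, and the window is deliberately small.
* **Phasic** $P_n = \mathrm{peak}_n - T_{n-1}$ (with $T_0 = 0$): the
  increment attributable to release evoked by stimulus $n$ alone.

Two readings of "8.4 ms after the stimulus" are possible: from the stimulus
onset, or from the end of artifact + rise. We adopt the latter, because it
is the only reading under which the prediction model below is
self-consistent: the entire current present at the peak, $P_n + T_{n-1}$,
decays for exactly 8.4 ms before the next tonic read-out. Percentage
outputs normalise by $P_1$, making all downstream comparisons
amplitude-free.

## IPSC kinetics

Decays are fit as $b + A\,[F_f e^{-t/\tau_f} + F_s e^{-t/\tau_s}]$ with
bounded Levenberg–Marquardt least squares, $t$ referenced to the detected
peak, $\tau \in [0.1, 100]$ ms, $F_f \in [0,1]$, and $F_s = 1 - F_f$.
Initialisation is classical peeling (log-linear tail regression seeds
$\tau_s$; the slow component is subtracted and the early residual seeds
$\tau_f$), followed by three perturbed restarts. Fits whose time constants
agree within 5% or whose minor fraction falls below 0.02 collapse to a
single exponential, reported with $F_f = 1$; the same branch serves as a
fallback when the two-component model is singular (genuinely
single-exponential data). The summary statistic everywhere is the weighted
decay time constant $\tau_w = F_f\tau_f + F_s\tau_s$.

Two window choices deserve comment:

* The default single-IPSC window runs from 0.2 ms after the peak to 20 ms
  after the peak. A window ending 9 ms after stimulus onset (a plausible
  alternative) leaves barely 1.5 slow time constants of data and was found
  too short to constrain $\tau_s$.
* Within trains the window is truncated at the next stimulus onset
  (10 ms), which *is* short. `fit_biexponential()` therefore fits the
  baseline freely by default (and records it), but the train pipeline
  (`fit_train_kinetics()`) anchors it: to the pre-stimulus mean for the
  first IPSC, and to the post-train quiescent level (median over 60–90 ms
  after the last stimulus, where the GABAergic residual has decayed to
  <0.1% but standing currents persist) for the last IPSC. Without
  anchoring, the baseline trades off against the slow component in the
  10-ms window and, at realistic noise (5 pA on a ~400 pA IPSC), drives
  $\tau_s$ to the boundary in roughly a third of fits — with catastrophic
  effect on the prediction stage. Anchoring uses only measured quiescent
  levels, so it introduces no circularity.

## The tonic-prediction model

Given biexponential fits of the first and last IPSC of a train, per-stimulus
kinetics are interpolated linearly in stimulus number and the tonic current
is predicted recursively:

$$T_n = (P_n + T_{n-1})\,D_n, \qquad
D_n = F_{fn} e^{-8.4/\tau_{fn}} + F_{sn} e^{-8.4/\tau_{sn}}, \qquad T_0 = 0.$$

Design decisions, each exposed as an argument:

* **Interpolation weights.** The default mode `"as_printed"` uses weights
  $(n-1)/20$ for every parameter regardless of the actual train length, so
  stimulus 20 receives $0.05\,x_{first} + 0.95\,x_{last}$ and never quite
  reaches the last-IPSC values. This is the model's original formulation
  and is kept as the default for fidelity; `"endpoint_exact"` (weights
  $(n-1)/(N-1)$) is offered for sensitivity analysis. The two differ by
  under half a percentage point of $P_1$ on the shipped presets.
* **The slow-τ interpolation start.** The original printed equations start
  the $\tau_{sn}$ interpolation from the *fast* time constant of the first
  IPSC — dimensionally inconsistent and treated here as a typographical
  slip. The default interpolates $\tau_{s}$ from its own first-IPSC value;
  `strict_tau_slow = TRUE` reproduces the printed line verbatim.
* **What decays.** The recursion decays the *entire* current present at the
  peak by $D_n$. A variant decaying only the phasic component
  (`recursion = "phasic_only"`, $T_n = P_n D_n + T_{n-1}$) is exposed for
  comparison; it omits the inter-stimulus decay of the accumulated tonic
  current and overestimates accordingly.
* **Phasic input.** The model consumes the *phasic* amplitudes
  $P_n = \mathrm{peak}_n - T_{n-1}$, not the raw peaks. With this choice
  the recursion is an identity for constant single-exponential kinetics
  (the whole peak current decays 8.4 ms to the next read-out); feeding raw
  peaks would double-count the residual.

`exact_superposition_tonic()` computes the assumption-free alternative,
$T_n = \sum_{k\le n} P_k D_k(8.4 + \mathrm{isi}\,(n-k))$, each stimulus
decaying with its own kinetics for its own elapsed time. For constant
single-exponential kinetics with isi = latency = 8.4 ms the two coincide to
machine precision, which the tests verify; for a 10-ms interval the
recursion sits a few percent above the superposition (e.g. 69.85 vs 64.90
for three 100-pA stimuli at τ = 10 ms), quantifying the approximation.

## Group arithmetic

The mGluR1/5 contribution to the train response is the difference between
the mean tonic current over stimuli 5–10 with and without the blocker,
summarised per group as an unpaired difference of means with
$\mathrm{SEM} = \sqrt{\mathrm{SEM}_A^2 + \mathrm{SEM}_B^2}$. (This
combination is occasionally printed with a minus sign inside the radical;
that form can go imaginary and is not a valid variance combination for
independent groups, so the quadrature sum is implemented.) The difference
is reported as drug − control, i.e. positive when the blocker unmasks
outward tonic current. Rebound firing uses *paired* cell-by-cell
differences instead, since each cell serves as its own control.
Hypothesis-testing machinery (ANOVA families, post-hoc tests) is a
non-goal; standard R routines apply directly to the tidy per-cell tables.

## Spiking metrics

Spikes are detected at upward crossings of dV/dt ≥ 20 mV/ms followed by a
peak ≥ −20 mV within 2 ms, with a 1-ms refractory rule; both thresholds are
package defaults chosen as standard for high-rate cerebellar neurons (the
underlying measurements report neither) and are exposed as arguments.
Half-width is measured at half of the threshold-to-peak amplitude with
sub-sample interpolation. Rebound firing compares the 300 ms after an
inhibitory train against the 500 ms before it,
$100\,(r_{post} - r_{pre})/r_{pre}$, with the post window anchored at train
*end* (anchoring at the last stimulus onset would differ by at most one
10-ms inter-stimulus interval). Rebound protocols hold the pre-stimulus
rate near 40 Hz, emulating the experimental bias current.

## The synthetic-data generator

The generator emulates the study conditions so that every stage has ground
truth:

* **IPSC trains** — events rise after a 0.6-ms delay along a saturating
  exponential (τ = 0.3 ms) to a peak 1.6 ms after stimulus onset, then
  decay biexponentially *referenced to the peak*; per-stimulus kinetics
  drift linearly from first- to last-IPSC values; peaks depress as
  $P_n = P_1[d + (1-d)e^{-(n-1)/k}]$ with plateau $d = 0.55$ and rate
  $k = 2$ stimuli (the depression model and its plateau are qualitative
  choices — per-stimulus phasic amplitudes are not reported numerically);
  an optional mGluR-like inward current builds as
  $a\,[1 - e^{-(n-1)/3}]$; Gaussian noise (default 5 pA) is added and
  artifact windows are flagged. Ground-truth tonic values are computed by
  the exact superposition of the generating decays at the measurement
  points.
* **Spiking traces** — a gamma-interval renewal process (shape 20,
  ISI CV ≈ 0.22, the regularity regime of CbN neurons) warped through a
  piecewise-constant rate profile: baseline, near-zero during the 500-ms
  train, a rebound rate for 300 ms, baseline again. A piecewise-linear
  spike template is added at each spike time. The near-Poisson alternative
  (low shape) would bias the post/pre rate ratio upward by several percent;
  regular firing keeps the percent-change estimator unbiased to <1 point,
  which the tests verify by Monte-Carlo.
* **Cohorts** — four sex × genotype presets (shipped as
  `inst/extdata/group_presets.yaml`) parameterised from the published group
  means: first/last weighted τ (2.3/4.4, 1.8/2.3, 2.5/3.2, 1.8/3.1 ms),
  spontaneous rates (65, 98, 92, 96 spikes/s), holding currents, TBOA
  currents, and CPCCOEt-sensitive rebound components (7, 39, 53, 25
  points). Evoked mGluR tonic amplitudes (0, −20, −24, −20 pA on a 400-pA
  first peak) encode the qualitative ordering of the group I mGluR
  contribution: absent in wild-type males, largest in females and mutant
  males. Per-cell variability is multiplicative lognormal with CV 0.3
  (positive-only parameters, heavy-ish tails typical of electrophysiology
  cohorts), applied as one multiplier each for amplitude, kinetic speed
  (jointly to all four τ, preserving fast ≤ slow), mGluR amplitude,
  spontaneous rate, and rebound increment. The drug condition removes the
  mGluR component and uses the preset drug rebound rate.

What the generator does **not** emulate: conductance-based membrane
dynamics, stochastic vesicular release (depression is deterministic),
series-resistance and space-clamp errors, non-stationary noise, true
stimulus artifacts (samples are flagged, not corrupted), or IPSP-locked
spike timing during trains. Passing tests therefore demonstrate that the
analysis recovers the *statistical structure it assumes*; robustness to
recording pathologies must be judged on real data.

## Verification strategy and problem sizes

The test suite checks each operation against independent oracles:
hand-unrolled recursions, closed-form decays, plain-arithmetic trace
reconstruction, and Monte-Carlo calibration. The deeper end-to-end property
is the predicted-vs-measured pattern: on cohorts of 11 cells per group,
predicted tonic current matches the measurement (within 2.5 points of
$P_1$, half the smallest preset mGluR fraction) only for the group
generated *without* an mGluR component, and exceeds it elsewhere — the
discrimination the analysis exists to make. Test problem sizes (200 noise
seeds for fit calibration, 50 cohort seeds for the pattern, $10^4$
bootstrap resamples for the SEM rule) were chosen so the whole suite
completes in minutes while keeping Monte-Carlo error well below the
tolerances tested.

## Known limitations

* The recursion inherits the model's own approximations (8.4-ms decay per
  10-ms interval; first/last interpolation); the superposition oracle
  bounds these at a few percent of $P_1$ under study-like kinetics.
* Last-IPSC fits ride on the decaying train residue; even anchored, their
  weighted τ is biased upward by ~5–10%. The bias is shared by any
  fit-the-last-IPSC protocol and partially cancels in the prediction.
* The mGluR component is modelled phenomenologically (amplitude + onset);
  no receptor kinetics are implied.
* `measure_train()` assumes uniform stimulus spacing when interpreting the
  8.4-ms latency; non-uniform trains are measured but the prediction model
  is not defined for them.
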