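# synaptrain

Analysis of evoked synaptic current trains and firing metrics in
cerebellar-nucleus (CbN) neurons.

CbN neurons receive high-frequency inhibition from Purkinje cells. During a
100-Hz train of stimuli the GABA-A IPSCs do not decay fully between stimuli,
so each evoked **phasic** current rides on an accumulating **tonic**
current — the component chiefly responsible for suppressing intrinsic CbN
firing. Whether the measured tonic current is fully explained by IPSC decay
kinetics, or is offset by a stimulus-driven inward current (group I mGluR
activation), is resolved by comparing the *measured* tonic current with the
tonic current *predicted* from IPSC kinetics alone. `synaptrain` implements
that entire analysis chain for patch-clamp data, plus a synthetic-data
generator with known ground truth so every stage is testable without
recordings.

## The model

IPSC decays are fit with a double exponential; the summary kinetic parameter
is the amplitude-weighted decay time constant

    tau_w = F_fast * tau_fast + F_slow * tau_slow .

Train decomposition, for stimulus *n* at onset *t_n* (baseline-subtracted,
outward positive): the tonic current *T_n* is read 8.4 ms after the IPSC
peak — i.e. at the next stimulus onset of a 100-Hz train, since artifact +
rise occupy 1.6 ms — and the phasic current is the increment above the
residual tonic level, `P_n = peak_n − T_{n−1}`.

The predicted tonic current uses only the biexponential fits of the first
and last IPSC of the train, interpolated linearly in stimulus number to
capture the within-train slowing of decay:

    T_n = (P_n + T_{n−1}) · D_n ,    T_0 = 0,
    D_n = F_fn · exp(−8.4/tau_fn) + F_sn · exp(−8.4/tau_sn),
    x_n = (1 − (n−1)/20) · x_first + ((n−1)/20) · x_last    (x = tau_f, tau_s, F_f, F_s).

An exact linear-superposition oracle
(`T_n = Σ_{k≤n} P_k · D_k(8.4 + isi·(n−k))`) is provided alongside the
recursion to quantify the model's approximation. Group comparisons use the
unpaired difference of means with SEMs combined in quadrature; the group I
mGluR contribution is the drug-minus-control difference of the mean tonic
current over stimuli 5–10. Current-clamp metrics cover spontaneous rate,
action-potential half-width, and post-inhibitory rebound firing (post/pre
rate change across a 500-ms inhibitory train, with the CPCCOEt-sensitive
component from paired cell-by-cell differences).

## Worked example

Generate a 20-stimulus 100-Hz train with a −20 pA mGluR-like inward
component, decompose it, fit the first/last IPSC kinetics, and compare the
predicted tonic current with the measurement:

```r
library(synaptrain)

params <- synth_ipsc_params(mglur_tonic_amplitude_pA = -20)
trace  <- generate_ipsc_train_trace(params, seed = 7)

decomp <- measure_train(trace)
head(decomp[, c("stimulus", "phasic_pA", "tonic_pA", "phasic_pct", "tonic_pct")], 5)
#>   stimulus phasic_pA tonic_pA phasic_pct tonic_pct
#> 1        1      401.    13.0       100       3.24
#> 2        2      326.     6.66       81.3     1.66
#> 3        3      298.     4.24       74.3     1.06
#> 4        4      261.     1.26       65.1     0.314
#> 5        5      243.     2.15       60.7     0.537

mean_tonic_5_10(decomp)   # mean tonic current, stimuli 5-10, % of first peak
#> [1] 1.01

fits <- fit_train_kinetics(trace)
fits$first
#> <biexp_fit> A = 406.5 pA, tau_f = 1.14 ms (F_f = 0.431), tau_s = 2.841 ms, weighted tau = 2.107 ms
fits$last
#> <biexp_fit> A = 252.4 pA, tau_f = 3.036 ms (F_f = 0.705), tau_s = 8.728 ms, weighted tau = 4.714 ms

pred <- predict_tonic(decomp$phasic_pct, fits$first, fits$last)
round(pred$tonic_pred[c(1, 5, 10, 20)], 2)   # predicted, % of first peak
#> [1] 2.98 4.23 6.48 9.59
round(decomp$tonic_pct[c(1, 5, 10, 20)], 2)  # measured, % of first peak
#> [1] 3.24 0.54 1.69 5.13
```

The predicted tonic current exceeds the measurement by several percent of
the first peak — the signature of the inward mGluR component this trace was
generated with (remove it, and prediction and measurement agree;
`autoplot(pred, measured = decomp$tonic_pct)` plots the comparison).

Whole cohorts run through one call:

```r
report <- run_pipeline(pipeline_config(n_cells_per_group = 11, seed = 1,
                                       out_dir = "run1"))
report$summaries$mglur_tonic_difference   # drug - control tonic, per group
report$rebound_component                  # CPCCOEt-sensitive rebound, per group
```

which writes per-cell fit/decomposition CSVs, predicted-vs-measured tables,
spiking metrics and a JSON manifest recording the seed and configuration.

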