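# Group presets for synthetic cerebellar-nucleus cohorts.
#
# Four sex x genotype groups. Kinetic presets encode the published group
# means for CbN IPSCs: weighted decay tau of the first IPSC (2.3 ms wild-type
# males, 1.8 ms wild-type females, 2.5 / 1.8 ms mutants) and of the last IPSC
# in the 100-Hz train (4.4, 2.3, 3.2, 3.1 ms). With a fast fraction of 0.75
# the (tau_fast, tau_slow) pair (tau_w / 1.5, 2 tau_w) reproduces each
# weighted tau exactly. Spontaneous rates are the published group means
# (65, 98, 92, 96 spikes/s); holding currents -565, -406, -491, -424 pA;
# TBOA-unmasked mGluR currents -297, -184, -419, -184 pA. Rebound rates start
# from a 40-Hz held pre-stimulus rate and encode the published
# CPCCOEt-dependent rebound components (7, 39, 53, 25 percentage points).
# Evoked mGluR tonic amplitudes (0, -20, -24, -20 pA on a 400-pA first peak)
# reproduce the ordering of the group I mGluR contribution: absent in
# wild-type males, largest in females and mutant males.
wt_male:
  name: wt_male
  sex: male
  genotype: "+/+"
  holding_current_pA: -565
  mglur_tboa_current_pA: -297
  ipsc:
    peak_amplitude_pA: 400
    tau_fast_first_ms: 1.5333
    tau_slow_first_ms: 4.6
    frac_fast_first: 0.75
    tau_fast_last_ms: 2.9333
    tau_slow_last_ms: 8.8
    frac_fast_last: 0.75
    mglur_tonic_amplitude_pA: 0
  spiking:
    baseline_rate_Hz: 65
    rebound_rate_Hz: 64.0
    rebound_rate_drug_Hz: 61.2
wt_female:
  name: wt_female
  sex: female
  genotype: "+/+"
  holding_current_pA: -406
  mglur_tboa_current_pA: -184
  ipsc:
    peak_amplitude_pA: 400
    tau_fast_first_ms: 1.2
    tau_slow_first_ms: 3.6
    frac_fast_first: 0.75
    tau_fast_last_ms: 1.5333
    tau_slow_last_ms: 4.6
    frac_fast_last: 0.75
    mglur_tonic_amplitude_pA: -20
  spiking:
    baseline_rate_Hz: 98
    rebound_rate_Hz: 68.0
    rebound_rate_drug_Hz: 52.4
mut_male:
  name: mut_male
  sex: male
  genotype: "m-/p+"
  holding_current_pA: -491
  mglur_tboa_current_pA: -419
  ipsc:
    peak_amplitude_pA: 400
    tau_fast_first_ms: 1.6667
    tau_slow_first_ms: 5.0
    frac_fast_first: 0.75
    tau_fast_last_ms: 2.1333
    tau_slow_last_ms: 6.4
    frac_fast_last: 0.75
    mglur_tonic_amplitude_pA: -24
  spiking:
    baseline_rate_Hz: 92
    rebound_rate_Hz: 72.0
    rebound_rate_drug_Hz: 50.8
mut_female:
  name: mut_female
  sex: female
  genotype: "m-/p+"
  holding_current_pA: -424
  mglur_tboa_current_pA: -184
  ipsc:
    peak_amplitude_pA: 400
    tau_fast_first_ms: 1.2
    tau_slow_first_ms: 3.6
    frac_fast_first: 0.75
    tau_fast_last_ms: 2.0667
    tau_slow_last_ms: 6.2
    frac_fast_last: 0.75
    mglur_tonic_amplitude_pA: -20
  spiking:
    baseline_rate_Hz: 96
    rebound_rate_Hz: 64.0
    rebound_rate_drug_Hz: 54.0
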