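Package: synaptrain
Title: Phasic and Tonic Decomposition of Evoked Synaptic Current Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis tools for patch-clamp recordings of cerebellar-nucleus
    neurons receiving high-frequency inhibitory input. Fits IPSC decays with
    a double exponential and computes amplitude-weighted decay time constants,
    decomposes 100-Hz evoked synaptic current trains into per-stimulus phasic
    and tonic components, predicts the accumulating tonic current from first-
    and last-IPSC kinetics with a recursive model (plus an exact-superposition
    oracle), quantifies pharmacological difference currents, and extracts
    spike-train metrics (spontaneous rate, action-potential half-width,
    post-inhibitory rebound firing). Ships a synthetic trace and cohort
    generator emulating four sex-by-genotype group presets so every stage of
    the pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
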