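Package: slicephys
Title: Whole-Cell Slice Electrophysiology Analysis with Ground-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of whole-cell patch-clamp recordings from acute brain
    slices: extraction of intrinsic membrane and firing properties from
    current-clamp step families (rheobase, F-I gain, adaptation index, input
    resistance, membrane time constant, sag ratio, per-spike waveform
    features), threshold-based detection and summarisation of spontaneous
    excitatory postsynaptic currents in voltage-clamp sweeps, quantification
    of optogenetically evoked 10 Hz train responses and their short-term
    dynamics, recording-level quality control, dendritic spine density
    computation, and the accompanying group statistics (lognormal-aware t
    tests, one-way ANOVA with Dunnett many-to-one comparisons). Includes a
    synthetic-data module (adaptive exponential integrate-and-fire membranes
    with sag, Poisson-timed biexponential synaptic events on drifting
    baselines, Tsodyks-Markram pulse trains, negative-binomial cell-by-gene
    tables) that provides ground truth for validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    multcomp,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
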