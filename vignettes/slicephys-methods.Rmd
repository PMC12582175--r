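---
title: "Methods: slice electrophysiology analysis with ground-truth simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice electrophysiology analysis with ground-truth simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicephys)
```

## Scope and design

`slicephys` implements the quantitative analysis of a whole-cell
slice-electrophysiology study of synaptic plasticity: extraction of
intrinsic membrane and firing properties from current-clamp step families,
threshold-based detection and summarisation of spontaneous excitatory
postsynaptic currents (sEPSCs) in voltage-clamp sweeps, quantification of
optogenetically evoked 10 Hz train responses, recording-level quality
control, dendritic spine-density arithmetic, group statistics, and a small
transcriptomic screening module. Because raw recordings of this kind are
rarely deposited, the package ships a first-class synthetic-data module
whose generators carry full ground truth; every analysis stage is validated
by parameter recovery against those generators, by closed forms, or by
statistical calibration.

All windows and epochs are specified in seconds, never in samples, so any
sampling rate is accepted; the fixtures and defaults use 20 kHz, the rate at
which such recordings are typically digitised. Current-clamp signals are mV,
voltage-clamp signals are pA with inward currents negative, as recorded.

## The sweep model and quality control

A recording is a `sweepset`: equal-length, uniformly sampled sweeps with
per-sweep stimulus epochs, a clamp mode, a holding level, and free-form
annotations. The on-disk format is a long CSV (`sweep`, `time_s`, `value`)
with a JSON sidecar; values are written with 17 significant digits so the
round trip is bit-exact. No binary formats are read or written; recordings
exported from acquisition software can be bridged to this dialect
externally.

Voltage-clamp sweeps begin with a brief hyperpolarizing test pulse
(default −5 mV for 250 ms) used to monitor access. The pulse response is
decomposed in the standard way: the capacitive-transient peak current
deviation from the 100 ms pre-pulse baseline gives the series resistance
`Rs = ΔV / I_peak`, and the steady-state deviation (mean over the last
50 ms of the pulse) gives the total resistance, with
`Rin = ΔV / I_ss − Rs`. This decomposition is validated against the
analytic two-resistor RC circuit: at 20 kHz sampling the first sample after
the step underestimates the true transient peak by under 10% for realistic
access time constants, which bounds the Rs error; Rin is recovered to well
under 5%.

Quality control applies four exclusion rules: resting membrane potential
more depolarized than −55 mV (−45 mV for anterodorsal-thalamus recordings,
which rest more depolarized), series resistance above 35 MΩ, and series or
input resistance changing by more than 25% over the experiment. The rules
are independent; the report lists every violated rule, and `pass` is true
exactly when none is. Change fractions are interpreted as magnitudes of
fractional change — a 30% rise in input resistance fails just as a 30% drop
does — which keeps the criterion monotone in worsening. Because the
monitoring comparison points are not standardised, ΔRs and ΔRin are
computed from the first and last sweeps' test-pulse metrics; per-sweep
metrics remain available if a different convention is wanted.

## The synthetic-data module

**Current clamp.** Cells are simulated as adaptive exponential
integrate-and-fire (AdEx) membranes with an additive slow sag conductance.
AdEx is a deliberate stand-in for real neurons: it reproduces every feature
the extractor measures — a smooth dV/dt acceleration through the 10 mV/ms
threshold criterion, spike-frequency adaptation via the recovery variable,
and an Ih-like sag via a hyperpolarization-activated gate — with fully
interpretable ground truth (R, C, spike times). Integration is fixed-step
exponential-Euler at the trace sampling interval; the same integrator run
with a 10× finer substep serves as the reference in convergence tests. When
the voltage crosses the AdEx spike cut, a stereotyped spike waveform
(0.3 ms rise to +30 mV, 0.6 ms fall to reset) is written into the trace so
that waveform-level feature extraction has something realistic to measure.
Ground truth counts spikes whose peak falls within the stimulus window,
matching the extractor's epoch convention. With the sag and adaptation
conductances at zero the model is a pure RC membrane and the integrator is
exact, which anchors the passive-property recovery tests.

Step families default to a −20 pA passive step plus a 0–400 pA ladder in
50 pA increments with membrane potential biased to −65 mV at sweep start,
the protocol typical of intrinsic-excitability characterisation. Voltage
noise defaults to zero because the recovery suites require exact count
ground truth; a noise term is available.

**Voltage clamp.** sEPSC sweeps are homogeneous-Poisson event times on
30 s sweeps; each event adds a negative-going biexponential kernel
(default rise 0.5 ms, decay 8 ms) normalized to unit peak, so configured
amplitudes are trace amplitudes. Amplitudes are lognormal — the empirical
shape of synaptic amplitude distributions and the reason the statistics
module log-transforms these measures. Gaussian noise (default 2 pA SD) and
an optional slow sinusoidal drift (a deterministic stand-in for the curved
baselines of real recordings) are added, plus the test-pulse response of a
fixed RC model. Events superpose linearly, which is both physiological and
the stress case for the detector's local-maximum logic.

**Evoked trains.** Per-pulse true amplitudes follow the Tsodyks–Markram
resource-utilization recurrence (release fraction `U`, recovery `tau_rec`,
optional facilitation `tau_facil`), scaled so pulse 1 equals the configured
first-pulse amplitude; kernels are placed at 10 Hz spacing and superpose.

**Cell tables.** The screening module's inputs are negative-binomial
per-cell counts of a target gene with configurable group means, dispersion
and verbatim cluster labels, emulating an annotated single-cell expression
table. Only the *screening logic* is in scope; reproducing published
atlas-scale statistics would require the external datasets themselves.

What the generators do *not* emulate: correlated (1/f) noise, electrode
drift other than the sinusoid, Rs changes over time, space-clamp error,
event-rate nonstationarity, and multi-compartment filtering of synaptic
currents. Passing recovery tests therefore demonstrates correctness of the
algorithms under controlled conditions, not performance on every real
recording.

## Intrinsic-property extraction

Spikes are local maxima reaching at least −10 mV within the stimulus epoch;
smaller deflections are not counted. The threshold is the last point before
the peak where dV/dt (central differences, mV/ms) rises through 10 mV/ms,
found by backward search from the peak — the criterion fixes the level, and
searching backward makes it robust to pre-spike wiggle. Crossings and
half-width levels are linearly interpolated between samples: at 20 kHz the
raw grid quantizes widths at 0.05 ms, and interpolation removes that bias.
Amplitude is peak minus threshold; maximum rise and decay slopes are taken
between threshold and the post-peak trough.

The F-I analysis counts spikes per step; rheobase is the smallest step
current with at least one spike; the gain is the ordinary least-squares
slope of count against current from 0 pA up to the step attaining the
maximum count (ties broken toward the lowest current) or 400 pA, whichever
comes first, and total spike output sums the counts over that range. When
no sweep spikes, rheobase is reported absent and the regression runs over
the full range (slope 0). The adaptation index is computed on the 1 s sweep
whose current is closest to twice rheobase ("approximately twice" is
operationalized as nearest available step, ties to the lower current):
`(N_first_half − N_second_half) / N_total`, peaks assigned to halves at the
epoch midpoint.

Passive properties come from small hyperpolarizing steps: the baseline is
the 100 ms pre-step mean; `Rin = |ΔV_max / I|` with ΔV_max the extremal
deflection during the step; the membrane time constant is a
single-exponential least-squares fit from step onset to the time of maximal
response (Levenberg–Marquardt, τ initialised from the 1−1/e crossing);
`Cin = TC / Rin` as an exact identity on the stored values; and the sag
ratio is the peak deflection over the mean deflection of the last 50 ms,
using absolute deflections so sag ≥ 1 by convention. The fit deliberately
starts at step onset as the procedure is usually stated; on clean RC traces
this is exact, and on traces with a capacitive artifact the first
millisecond can bias τ slightly — a sensitivity worth knowing about, not
corrected for here.

## Spontaneous-event detection

The detector is threshold-based with the standard parameter set: negative
peak direction, 8 pA amplitude threshold, 5 ms local-maximum period, 10 ms
search period, 1 ms averaged local baseline, 30 ms decay search period, and
a curved baseline. Choices the parameter names leave open were fixed as
follows:

* **Curved baseline** — a rolling median over 0.5 s, computed on a ~1 kHz
  decimated copy and interpolated back. A median follows slow drift while
  being insensitive to the events themselves at physiological rates; 0.5 s
  is slow enough to not flatten 30 ms events and fast enough to track
  multi-second drift.
* **Search period** — interpreted as the post-crossing window within which
  the event peak (most negative point) is located.
* **Candidate generation** — primary candidates are downward threshold
  crossings of the baseline-subtracted trace. An event arriving while the
  trace is still below threshold from an earlier event produces no fresh
  crossing, so secondary candidates are taken from local minima of a
  lightly smoothed (0.25 ms boxcar) trace, accepted only when the drop from
  the preceding turn reaches the threshold. Candidates whose peaks fall
  within the 5 ms local-maximum period of a larger candidate are merged
  into it.
* **Onset** — found by walking back from the peak until the smoothed trace
  recovers to 10% of peak depth (rise start on a quiet baseline) or falls
  half a threshold below its running maximum (the turn point of an
  overlapping event). The local baseline is the 1 ms of raw signal before
  this onset, and amplitude is local baseline minus the smoothed peak
  depth; reading the peak from the smoothed trace suppresses the
  noise-extreme bias of a raw windowed minimum, keeping the amplitude
  estimator unbiased within a few percent and the 8 pA threshold sharp
  (≤5% of 5 pA events and ≥95% of 15 pA events detected at 2 pA noise).
* **Noise rejection** — published workflows reject noise events manually;
  an automated pipeline must be deterministic, so events with onset-to-peak
  rise times outside 0.1–5 ms are rejected instead. The bounds are
  parameters of `detection_params()` and can be adjusted or disabled.

Summaries follow the per-sweep convention: the first second of each sweep
(containing the test pulse) is discarded, so frequency on a 30 s sweep is
the count divided by 29 s; with optogenetic stimulation present the first
2 s are discarded and the divisor is 28 s. Mean amplitude averages all
events in the sweep. Kinetics come from the averaged event — peaks aligned
over a window 5 ms before to 30 ms after the peak (matching the decay
search period), locally baseline-subtracted — with the half-width
interpolated at half the averaged peak and the decay constant from a
single-exponential fit. The acute-pharmacology time course expresses each
sweep's frequency as a percentage of the mean of the first two (baseline)
sweeps; cells with zero baseline frequency are flagged and excluded from
percentage aggregation.

A note on analysis units: per-sweep summaries are aggregated to cell-level
means before group statistics. Published degrees of freedom in this
literature are not always reconcilable with a single choice of unit
(sweeps vs cells vs dendrites), so the aggregation level is left to the
caller; the pipeline uses cells.

## Evoked-train analysis

Trials (typically 4–5) are averaged point-wise before measurement —
averaging first, then peak-picking, avoids the positive bias that
peak-picking noisy single trials would add. For each of the 10 pulses the
baseline is re-measured as the 5 ms pre-pulse mean; at 10 Hz with ~8 ms
decay kernels the trace has not fully returned to baseline when the next
pulse arrives, and re-measuring removes that bias from later pulses.
Amplitude is baseline minus the most negative point in the 50 ms
post-pulse window; the per-pulse area is the trapezoidal integral of
(baseline − signal) over the same window, in pA·ms — baseline-subtracted,
since a raw integral would conflate holding current with charge.
Short-term dynamics are the amplitudes normalized to pulse 1
(`normalized[1] ≡ 1`). Against noise-free Tsodyks–Markram ground truth the
normalized profile matches the recurrence to well under 5%; the residual
error is kernel overlap at 10 Hz, which grows with the kernel decay
constant and is negligible for decay ≤ 20 ms.

## Group statistics

Spine density is count/length per dendrite after the inclusion rules:
branches shorter than 40 µm are excluded (short segments make density
unreliable), and at most five apical and five basal dendrites per neuron
are admitted, in the order supplied.

The distribution-shape test runs Shapiro–Wilk on raw and log-transformed
values and classes the sample as normal, lognormal (whichever passes at
α = 0.05; higher W on a tie), or other. The package then follows the
empirical convention for these measures: spine counts and sEPSC
frequency/amplitude are *always* log-transformed before testing — the
transform is fixed per measure class rather than re-decided per dataset, so
that identical measures are always tested on the same scale — while other
measures consult the shape test when large enough and are tested raw
otherwise. Tests are two-tailed Student t tests with pooled variance
(matching the df = n1 + n2 − 2 convention of the field's reports; Welch
would change df), paired where the design says so, with degenerate cases
(identical groups, constant paired shifts) handled overflow-safely. Group
summaries (mean, SD, SEM = SD/√n, n) are always reported on the raw scale.

Many-to-one comparisons use one-way fixed-effects ANOVA with Dunnett
adjustment; the adjusted p-values come from the multivariate-t distribution
(via `multcomp::glht`), which handles unbalanced designs. Calibration is
verified by simulation: the log-scale t test's type-I error and the Dunnett
family-wise error rate are both 5% within Monte-Carlo tolerance over 1000+
null replicates. With two groups the Dunnett comparison reduces to the
plain t test.

## Transcriptomic screen

Cluster labels are mapped to putative layers by exact substring match
against the annotation token lists ("L2 IT" and "L2/3 IT" → L2/3; the
L4/L5 list → L5; the L6 list → L6), with the retrosplenial-specific cluster
"133_L2 IT RSPv-POST-PRE" mapped to "L2/3 LR" with priority over the
generic L2 rule — this cluster is the transcriptomic correlate of the
low-rheobase neurons of granular retrosplenial L2/3. Matching is by the
printed tokens, not regex, because the lists are enumerated verbatim;
unmatched labels become "unassigned" rather than an error. Contrasts
delegate to the statistics module (t test for a pair, ANOVA + Dunnett for
many-to-one) on raw per-cell counts — screens run on synthetic tables where
the count scale is the ground truth; normalisation choices for real atlas
data are out of scope — and additionally report each group's fraction of
cells with non-zero counts.

## Pipeline and reproducibility

`run_pipeline()` wires the stages together under a single configuration
(YAML-serialisable, validated, with a mandatory master seed from which
every per-cell simulation seed is derived): simulate two groups of cells →
test-pulse QC → event detection → per-sweep summaries → cell-level
log-scale t test. Outputs are fixed-format TSV tables plus a JSON manifest
recording package and R versions, the full configuration, seeds, and md5
hashes of every table; identical configurations produce byte-identical
tables. The demo configuration (6 control cells at 1.0 Hz vs 6 treated
cells at 1.8 Hz, 3 × 30 s sweeps each) is sized to detect its constructed
effect with high power while running in seconds.

## Problem sizes used in validation

The shipped validation suites use: 30–50 random cells for passive
recovery; 10 × 30 s sweeps per rate for event-rate recovery at 0.5–5 Hz;
5 × 30 s sweeps for kinetics and sensitivity; 1000 replicates for t-test
calibration and 1000–2000 for Dunnett family-wise error; and the demo run
twice for determinism. These sizes give Monte-Carlo error comfortably
below the tolerances being checked.

## Known limitations

* No ABF/NWB binary I/O; recordings must be bridged to the csv+json
  dialect.
* The detector has no template-matching or deconvolution mode and no
  positive-direction (IPSC) mode.
* No hierarchical (sweep-within-cell) modelling; analysis units are chosen
  by the caller.
* Series-resistance compensation of event amplitudes is not modelled.
* The exponential fits are single-order; multi-exponential decays are
  summarised by their dominant constant.
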