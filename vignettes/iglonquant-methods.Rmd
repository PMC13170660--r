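---
title: "Methods: calcium-transient detection, hyperactivity classification, and image quantification in iglonquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium-transient detection, hyperactivity classification, and image quantification in iglonquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iglonquant)
```

`iglonquant` implements the cell-level quantification stack used to study
how anti-IgLON5 autoantibodies change neuronal activity and Tau
localisation in cultured neurons: conversion of ROI fluorescence movies to
ΔF/F<sub>0</sub>, template-matching detection of calcium transients,
control-referenced hyperactivity classification, somatodendritic
Tau-missorting intensity statistics, surface-cluster quantification on
dendrite masks, tangle-fraction counting, and one-site antibody-binding
(K<sub>d</sub>) fits. Because no raw imaging data of this kind are publicly
deposited, the package ships a synthetic-data generator with exact ground
truth; every quantification stage is validated against that truth. This
vignette records the models, the parameters that matter, and the design
choices made where the underlying methodology left the details open.

## 1. ΔF/F0 conversion

Raw per-ROI fluorescence `F` is converted to
`ΔF/F0 = (F − F0)/F0` with a scalar per-ROI baseline. `compute_baseline()`
tiles the trace into consecutive non-overlapping windows of `window_s`
seconds (default 60 s); the baseline is the mean over windows of each
window's 50th percentile. Two conventions had to be fixed:

* **Tiled, scalar baseline.** "The average of the 50th percentile across a
  60-s window" admits both a rolling, time-varying baseline and a tiled,
  scalar one. The package uses tiled windows and a scalar F<sub>0</sub> —
  the literal reading of "taking the average of the window percentiles" —
  and documents the contract so a rolling variant could be added behind the
  same interface. A trailing partial window at least half a window long is
  kept as its own window; a shorter fragment is merged into the previous
  window, so no frame is ever discarded.
* **Percentile convention.** Linear interpolation between order statistics
  (R quantile type 7). The test oracles use the same convention.

For a trace whose events occupy fewer than half the frames of every
window, the window median — and hence F<sub>0</sub> — equals the true
baseline exactly; this is tested, as are gain invariance
(`ΔF/F0(kF) = ΔF/F0(F)` to 1e−12) and weak monotonicity of the baseline.
Non-finite fluorescence values are a hard error: silent imputation would
corrupt every downstream event statistic.

## 2. Transient detection

`detect_events()` slides a window of template length along each
ΔF/F<sub>0</sub> trace and compares it with a library of
difference-of-exponentials waveforms
`w(t) = exp(−t/τ_decay) − exp(−t/τ_rise)`, peak-normalised, one per
(rise, decay) pair. Defaults: rise {0.05, 0.1, 0.2} s × decay
{0.3, 0.6, 1.2} s, 3 s long, spanning GCaMP6f-like kinetics from fast
single events to slower multi-spike envelopes. A window is a candidate
event when

* its best Pearson correlation against the library reaches the
  **similarity threshold 0.75**, and
* its peak ΔF/F<sub>0</sub> reaches the **minimum amplitude 0.01**.

Choices fixed here, with rationale:

* **Similarity = Pearson correlation** of the mean-subtracted window
  against the template: scale-free, bounded in [−1, 1], so 0.75 is a
  meaningful cut regardless of event size.
* **Amplitude gate on the window peak** (not on a template-fit
  coefficient), matching the ΔF/F<sub>0</sub> units in which the minimum
  amplitude is quoted.
* **Greedy non-maximum suppression**: candidates are accepted in order of
  decreasing similarity (ties: earlier onset) and suppress later candidates
  within half a template length. Events closer than that merge — which is
  why the perfect-recall guarantee is stated for transients separated by
  more than one template length.
* **No zero-padding**: windows must fit inside the trace, so events in the
  last template-length of a recording can be missed. At 180 s this loses at
  most ~1.7% of the recording.

On noiseless synthetic traces with injected transients (amplitude ≥ 0.1,
gaps > template length) detection has 100% recall and zero false
positives; at noise SD 0.02 ΔF/F<sub>0</sub> and amplitude 0.2 — an
indicator-realistic operating point — recall and precision stay above 0.9
(both are acceptance-tested). Spike rates are reported in spikes/min,
including zero-event ROIs.

## 3. Hyperactivity classification

Per timepoint, the control (pCtrl) group defines the reference:
`threshold = mean + 2 × SD` of control spikes/min, with the **sample SD
(n−1 denominator)** — the small-sample convention; the choice is fixed so
the test oracles match. Classes are exhaustive and mutually exclusive:

* *silent*: rate 0;
* *hyperactive*: rate strictly greater than the threshold (a tie is
  *active*, because the criterion is "larger than");
* *active*: everything in between.

"Inactive" and "silent" are treated as synonyms for the zero-rate class.
An all-zero control group yields threshold 0 — permitted, but flagged with
a warning since every spiking neuron then counts as hyperactive.
Calibration: with treated rates drawn from the same Gaussian as controls
(n = 300/group), the median hyperactive fraction across 200 seeds falls in
[0.5%, 6%], consistent with the ~2.3% one-sided 2σ tail plus sampling
error; with a 3× rate effect the treated fraction exceeds the control's in
at least 95% of seeds. Group means can be normalised to a designated
reference group/timepoint (e.g. untreated cultures at 60 min) via
`normalize_rates()`.

## 4. Image statistics

**Tau missorting.** The somatodendritic missorting statistic is the
mean Tau fluorescence over the cytoplasmic (soma-minus-nucleus) region:
`MFI = (RawIntDen_soma − RawIntDen_nucleus) / (Area_soma − Area_nucleus)`.
ROI masks are *inputs* (manual or synthetic); the package deliberately does
no automatic soma segmentation, mirroring the manual-ROI workflow.
Intensities are used as-is (no background subtraction). The implementation
is tested for exact equality with a brute-force pixelwise cytoplasmic mean
and is invariant to intensity outside the soma.

**Surface clusters.** The segmentation recipe of the original interactive
pipeline is not published, so a standard puncta recipe is used and every
knob exposed: Gaussian smoothing (σ = 1 px), Otsu global threshold,
components restricted to the Otsu-thresholded MAP2<sup>+</sup> dendrite
mask, **8-connectivity**, minimum area 2 px. Cluster density is
`# clusters / MAP2+ area` (projected 2-D area, per the density formula's
definition; skeleton length would be an alternative the package does not
claim to reproduce). Radius is reported as the equivalent-circle radius
`sqrt(area/π)`. The fixtures validate the *contract* — exact count and
density recovery for 0–20 disjoint puncta — not parity with the
unpublished pipeline.

**Nuclei and tangle fraction.** Nuclei are counted by Otsu threshold,
8-connected components and a size filter (default 5 px); touching nuclei
merge — a documented limitation, avoided in the fixtures by disjoint
placement. The tangle fraction is `100 × # tangles / # DAPI+ nuclei`.

## 5. One-site binding fits

Dose–response curves are fitted by unweighted nonlinear least squares
(Levenberg–Marquardt, `minpack.lm`) to the one-site model
`MFI(c) = MFI_max · c / (Kd + c)`, with multi-start initialisation
(MFI<sub>max</sub> at the largest observed MFI; K<sub>d</sub> at the
concentration nearest half-max plus five log-spaced starts) and the
lowest-RSS converged fit reported. A one-parameter variant
`MFI = MFI_max · c / (0.5·MFI_max + c)` is available as
`model = "half_max_printed"` for literal reproduction of that
parameterisation; it is not the default because it equates a fluorescence
quantity with a concentration, whereas the two-parameter form leaves
K<sub>d</sub> a free concentration-scale parameter, as "one
site-specific binding" requires. Fits are unit-equivariant: fitting in nM
instead of µg/ml scales K<sub>d</sub> by exactly the conversion factor
(for IgG at 150 kDa, 1 µg/ml ≙ 6.67 nM; `mass_to_molar()`). Noiseless
curves on the standard 0.01/0.1/1/10 µg/ml grid recover
(MFI<sub>max</sub>, K<sub>d</sub>) to 1e−6 relative; at 5% multiplicative
noise the median relative K<sub>d</sub> error over 100 seeds stays within
15%. The fit accepts per-image means or per-neuron values alike; what was
supplied is the caller's choice and is visible in the stored data of the
fit object.

## 6. What the synthetic data do and do not emulate

The generator reproduces the *acquisition regimes* of the assays:

* **Traces**: 180-s recordings at 8 Hz (frame count
  `floor(duration × fs)`). Spiking is homogeneous Poisson per neuron with
  log-normal rate heterogeneity across neurons (mean-one multiplicative,
  CV 0.6) — the simplest model matching a spikes/min readout; treatment
  effects multiply each neuron's rate. The indicator response is a
  peak-normalised difference of exponentials (rise 0.1 s, decay 0.6 s,
  GCaMP6f-like); responses superpose linearly on a multiplicative
  `baseline_F · exp(−bleach_rate·t)` envelope, plus additive Gaussian
  noise. Default conditions, chosen once as culture-realistic: control
  mean rate 2 spikes/min, baseline 100 a.u., noise SD 2 a.u.
  (0.02 ΔF/F<sub>0</sub>-equivalent at that baseline), no bleaching.
  No shot noise, bursting, or calcium-buffering biophysics; traces are
  generated at ROI level, not extracted from rendered movies. Reported
  inter-neuron variance and noise magnitudes are free parameters of the
  generator, not claims about any particular culture.
* **Images**: disk somata with strictly interior disk nuclei, straight
  neurites/dendrites, disk puncta, uniform intensities plus optional
  Gaussian noise (clipped at zero). A controllable `allocation_somatic`
  fraction splits a fixed Tau budget between the cytoplasm and the
  neurites, so the missorting statistic is known exactly. Puncta are
  placed disjointly with a guard gap inside the dendrite mask (bounded
  retries, then a generation error). Stored truth is, by invariant,
  exactly what the matching quantification operation returns on the
  noiseless rendering.
* **Binding curves**: `MFI_i = MFI_max·c_i/(Kd+c_i)·(1+ε_i)` with
  `ε_i ~ N(0, noise_cv)` on the 0.01/0.1/1/10 µg/ml grid.

Passing these tests shows the *computations* are correct on data whose
truth is known; it does not certify performance on real movies with
drift, neuropil contamination, overlapping ROIs, or focus changes — those
effects are out of scope by design.

## 7. Determinism, problem sizes, and formats

Every stochastic operation takes an explicit integer seed; run-level
master seeds expand into per-operation seeds via `derive_seeds()`.
Identical seeds give bitwise-identical outputs, including CLI files. The
validation suite uses desk-scale sizes chosen to keep each property sharp
but cheap: 100–1000 neurons for trace statistics, 200 seeds for the null
calibration, 50 missorting images, 21 cluster fixtures, 100 binding
seeds — the acceptance report records the size next to every number.

Interchange formats are deliberately plain: traces and events as CSV
(header row, `time_s` first column), images as multi-page 32-bit float
TIFF with a JSON manifest mapping channel role → page and intensity
scale, ROI masks as a labelled 16-bit TIFF (0 background, 1 soma
cytoplasm, 2 nucleus), configuration as schema-validated YAML, reports as
JSON. Group statistics (ANOVA and post-hoc testing of the resulting rate
tables) are routine and left to standard tools.
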