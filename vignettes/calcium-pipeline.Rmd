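---
title: "Calcium transients, network synchrony and single-cell screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium transients, network synchrony and single-cell screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroflux)
```

neuroflux analyses fluorescence recordings of cultured neurons loaded with a
calcium indicator, together with companion single-nucleus RNA-seq count
matrices. This vignette is the package's account of the methods: the models,
the tunable parameters and why their defaults are what they are, the
numerical choices, and the limits of what the built-in simulations can show.

## The recording model

Recordings are movies (or per-ROI trace tables) sampled at regular frame
intervals; the canonical geometry throughout is 1000 frames at 0.2 s
(about 3 min per field of view). A neuron's fluorescence trace is modelled
as

```
F(t) = baseline + drift(t) + sum over spikes of k(t - t_spike) + noise(t)
```

where the indicator kernel `k` rises linearly over `rise_frames` frames
(default 1) to `amplitude` and decays exponentially with time constant
`tau_decay_s` (default 0.5 s), drift is one sinusoidal cycle of amplitude
`drift_amp` over the recording, and the noise is i.i.d. Gaussian with
standard deviation `noise_sd`. The kernel peak is anchored on the spike
frame itself, so detected peak frames are directly comparable with ground
truth spike frames.

Spiking is a per-neuron Poisson process at `rate_hz` (default 0.05 Hz,
sparse cultured-network activity) plus *shared network events*: a global
Poisson process at `sync_rate_hz` (default 0.2 Hz) that each neuron joins
independently with probability `sync_p`. This single knob moves the
population continuously from independent firing (`sync_p = 0`) to perfect
network-wide co-activation (`sync_p = 1`) and is what the eigenvalue
synchrony readout is validated against. Spikes are quantized to frames and
collisions merged, so trains are strictly increasing frame sequences.

Defaults for the signal-to-noise regime (`amplitude = 6`, `noise_sd = 1`,
`tau_decay_s = 0.5`) describe a clearly visible transient: six noise SDs at
the peak, decaying over two to three frames. Real recordings vary widely in
SNR; the amplitude here is a simulation working point, not a claim about any
particular dataset, and the detector tests sweep noise levels around it.
One caveat is documented prominently: a window-3 median filter erases
one-frame impulses, so simulated transients must outlast a single frame
(decay spanning at least 2 frames) to be detectable — the default
`tau_decay_s` of 0.5 s at 0.2 s frames satisfies this.

## Trace preparation

**Background subtraction** estimates, per trace (or per pixel), a running
20th-percentile baseline over a sliding window (default 150 frames = 30 s)
and subtracts it. Two numerical details matter. First, the percentile is
evaluated at anchor frames every quarter-window and linearly interpolated,
which makes the cost independent of the window length; the interpolation is
exact for baselines varying on scales much longer than a quarter window.
Second, a lower percentile of a noisy signal sits systematically below the
true baseline (about 0.84 SD for Gaussian noise at the 20th percentile) and
lags on slopes, so a refinement pass re-centres the estimate on the running
mean of quiescent frames, with frames more than two robust SDs above the
provisional baseline masked out so transients cannot bias the baseline
upward. The full baseline is returned as an attribute; adding it back
reconstructs the input exactly.

**ROI detection** segments the temporal-mean image: Gaussian smoothing
(sigma 1 px), a threshold at `mean + 3 SD` of the smoothed image, connected
components, and an area filter (defaults 20–500 px). It is deterministic
and an empty result is a valid outcome, not an error. Segmentation operates
on the raw stack's mean brightness: stained cell bodies are bright whether
or not they fire, and removing the per-pixel temporal baseline first would
erase exactly that standing contrast. The detector is a documented stand-in
validated against simulated ground truth only — curated ROI selection in
real software involves human checks this package does not model.

**Median filtering** replaces each sample by the median of a centred
window (default 3 frames, the standard impulse-noise filter for these
recordings). Edges use shrunken asymmetric windows rather than padding, so
no data is invented at the recording boundary. The filter records its
window on the output because the spike detector needs to know how much the
smoothing attenuated the noise (see below).

## The spike criterion

A calcium transient is operationalized as a *fast* (< 400 ms) increase of
the fluorescence signal above *2 or more standard deviations of the
background*. The implementation makes each clause precise:

- **Noise scale.** `sigma` is the SD of the background, per ROI, estimated
  as 1.4826 × MAD. Two refinements keep this faithful at realistic spike
  rates. The estimate is computed on background frames only: a provisional
  scale flags supra-threshold runs, which are masked together with their
  decay tails before the final estimate — otherwise transient tails shift
  the median and inflate the scale by several percent. And because the
  median filter shrinks white noise by a known factor (0.670 for window 3;
  computed by numerical integration of the order-statistic density for
  other odd windows), the estimate is divided by that factor so the
  threshold stays in units of the *unsmoothed* background SD. A known
  scale can also be supplied directly (`sigma =`), which makes the
  criterion fully deterministic on constructed traces.
- **Threshold.** Frames with `F - center >= k_sd * sigma` (default
  `k_sd = 2`) are supra-threshold, with `center` the trace median —
  quiescent segments of a percentile-baseline-subtracted trace sit
  slightly above zero, so thresholding absolute values would silently
  tighten or loosen the criterion.
- **Rise time.** At a 0.2 s frame interval, "< 400 ms" is one inter-frame
  step (`floor((max_rise_s - eps) / frame_interval_s)`, recomputed for
  other sampling rates). The first event of a supra-threshold run is
  accepted if the signal was at background level (within one SD of the
  centre) no more than one step plus the filter half-width before the
  peak, or if it climbed by the full threshold within the step budget
  between onset and peak, or if the rise is clipped by the recording
  start. The two disjuncts cover complementary failure modes of a single
  literal rule: a centred median filter can delay the apparent peak by one
  frame, and pre-peak samples can ride up on noise; a slow ramp satisfies
  neither, however high it ends.
- **Multiple events per run.** Consecutive supra-threshold frames caused by
  one transient yield one spike, located at the run maximum (earliest frame
  on ties). Later local maxima within the same run are separate spikes only
  if they come with their own full-size fast climb — bursts riding on a
  decaying transient are counted, plateau wiggles are not.

A trace with zero noise scale (constant) yields no spikes, with a warning.
Raising `k_sd` cannot increase counts in practice, though in pathological
twin-peak traces a higher threshold can split one merged run into two; the
monotonicity tests use realistic traces where the property holds.

At the default settings the detector's operating point is set by the
criterion itself: with 2-SD thresholding, a 1000-frame recording yields on
the order of one noise crossing per neuron, so at 0.05 Hz (ten true spikes
per recording) precision near 0.9 is the natural ceiling — this is a
property of the criterion, not of the implementation.

**Activity summaries** are per-ROI spike rates in spikes/min and the
*active fraction*, the share of ROIs with at least one detected spike.

## Eigenvalue synchrony

Spike trains are binarized (1-frame bins by default), pairwise zero-lag
Pearson correlations form an N×N matrix with unit diagonal, and its
eigenvalue spectrum summarises network coordination: independent firing
gives a flat spectrum near 1, coordinated firing concentrates variance in
the leading eigenvalue, up to N for perfect synchrony. The scalar index is
`lambda_max / N`, in (0, 1]; the full spectrum is always reported alongside
so that any other functional of it can be recomputed. Silent ROIs are
retained with zero off-diagonal correlation (so N stays the ROI count)
unless explicitly dropped. Trace-based correlation is available by passing
the trace matrix rather than the binarized trains.

The validation harness (`sync_curve`) runs the *entire* chain — simulate,
render, subtract background, median-filter, detect, binarize, correlate,
eigen-decompose — on a grid of `sync_p` values with many seeds, and the
companion circular-shift permutation null (`sync_permutation_null`)
destroys inter-neuron timing while preserving each train's count and
autostructure. Observed indices at `sync_p = 0` should be ordinary draws
from that null; at high `sync_p` they should exceed its 99th percentile.

## Group statistics

Condition comparisons mirror the standard nonparametric chain: a
Kolmogorov–Smirnov normality screen (with sample mean and SD plugged in,
Lilliefors-style; the p-value is flagged approximate because the reference
parameters are estimated), a Kruskal–Wallis omnibus test with tie
correction, and Dunn's pairwise mean-rank comparisons with tie-corrected
standard errors. Holm is the default multiplicity adjustment — it dominates
Bonferroni at the same familywise guarantee — with Bonferroni available for
the conservative variant. The unit of analysis (per-cell rates vs per-field
synchrony indices) is always explicit in the pipeline, never implicit.

## The single-cell screen

Counts are normalized per cell to a common total (default 10,000) and
log1p-transformed. This deliberately replaces regularized variance
stabilization: the screen's statistic is the Wilcoxon rank-sum test, which
depends on normalization only through per-cell scaling, and this
substitution is the package's one documented methodological deviation from
heavier single-cell toolchains — absolute DEG counts from real datasets
processed with other normalizations are not expected to match exactly.

Per cell type and condition contrast, every gene gets a two-sided rank-sum
p (exact enumeration when both arms have ≤ 10 cells and no ties; normal
approximation with tie correction otherwise), a log2 fold change computed
on de-logged group means with a 1e-9 epsilon guard, Benjamini–Hochberg
adjustment across genes, and a significance flag at `p_adj < 0.05` and
`|log2FC| > 0.25`. Cell-type composition across conditions is compared with
per-pair two-proportion chi-square tests (no continuity correction, matching
the textbook Pearson statistic), BH-adjusted across all (cell type, pair)
tests.

The count simulator draws negative-binomial counts (variance
`mean + mean^2 / dispersion`; default dispersion 2, typical UMI
overdispersion) for a conditions × cell-types design (defaults: three
conditions mirroring a control and two treatment media, four cell types).
Planted genes get their mean multiplied by `2^log2fc` in one random
(cell type, non-reference condition) group. One design choice deserves
emphasis: within each affected group, up- and down-regulated genes are
mixed in the linear-space proportion that leaves the group's expected
library size unchanged. One-sided planting shifts library totals by around
10%, and per-cell total-count scaling then converts that composition shift
into a real distributional difference in every null gene — which a rank
test at 200 cells per arm reliably detects, wrecking the empirical false
discovery rate through no fault of the test. Balanced planting isolates
per-gene differential expression from this artifact; real datasets with
strongly one-sided regulation remain vulnerable to it under any total-count
normalization, which is a known limitation of the approach, not of the
simulator.

## Orchestration and reproducibility

`run_pipeline()` drives end-to-end runs from a single YAML (or list)
config: a `seed`, a `calcium` section (frame interval, duration, per-
condition field counts and simulator overrides, detection settings) and/or
a `counts` section (simulator settings, contrasts, cell types). Outputs are
plain CSV/JSON files plus a manifest with the config snapshot, the seed and
an MD5 digest of every output; identical config and seed reproduce the
bundle byte for byte. All randomness descends from one root seed through
named substreams (a deterministic 31-bit hash per component), so individual
stages can be pinned in tests. Frames are 0-based everywhere on disk, and
times in seconds are `frame_index * frame_interval_s`.

Example config:

```yaml
seed: 1
calcium:
  frame_interval_s: 0.2
  duration_s: 200
  conditions:
    - label: control
      n_fields: 3
      sim: {n_neurons: 50, sync_p: 0.6}
    - label: treated
      n_fields: 3
      sim: {n_neurons: 50, sync_p: 0.2}
counts:
  sim: {n_genes: 2000, cells_per_group: 200, de_fraction: 0.1, planted_log2fc: 1}
  contrasts: [[APPV717L, control], [APPWT, control]]
```

## Problem sizes and what the tests show

The test suite and the acceptance script size their simulations to run
comfortably on a single CPU: detector recovery uses 100 neurons × 1000
frames; the synchrony grid uses 50 neurons × 1000 frames × 20 seeds per
grid point; the familywise-error simulation uses 1000 null replicates of
3 × 30 observations; DEG calibration uses 5000 genes × 400 cells (null)
and 2000 genes × 2400 cells (planted effects).

Passing these checks shows that the implementation is internally coherent
against ground truth its own generator defines: a criterion that separates
fast from slow rises, a synchrony index monotone in a known synchrony knob,
rank tests at their nominal level, a screen that recovers planted fold
changes at calibrated error rates. It does not show performance on real
recordings: the generator has no motion, no neuropil contamination, no
photobleaching beyond slow drift, no indicator saturation, disk-shaped
non-overlapping cells, and Gaussian noise. Real single-cell data likewise
bring batch structure, mean-dependent dispersion, dropout and ambient
contamination that the negative-binomial simulator does not emulate. The
package's claims end where those simplifications begin.

## Known limitations

- The spike criterion is a threshold rule, not spike inference; no
  deconvolution is attempted, and sub-frame spike timing is unavailable.
- Noise flickers can mimic fast rises in principle; at the default
  threshold this costs about 0.1% of frames in false peaks.
- The ROI detector assumes compact bright somata on a dark background;
  overlapping or dim cells are out of scope.
- Under the global null, one marginal BH call among thousands of genes is
  expected in roughly one run in twenty at any fixed seed; the calibration
  checks use the criterion's own tolerances rather than certainty.
- Dunn's test adjustment flavour and the analysis unit for frequency
  comparisons are exposed as options (`adjust`, and the explicit choice of
  per-cell vs per-field observations) rather than fixed, since conventions
  differ between tools.
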