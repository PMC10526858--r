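# neuroflux

Analysis of calcium-imaging recordings from cultured human neuronal
networks, and of companion single-nucleus RNA-seq count matrices — the
kind of data produced when iPSC-derived neuron/astrocyte co-cultures are
exposed to amyloid-β and their spontaneous activity and transcriptomes are
read out.

The package implements four things end to end:

1. **Calcium-transient detection.** Per-ROI fluorescence traces are
   background-subtracted (running 20th-percentile baseline with a
   quiescent-mean refinement), median-filtered over 3 frames, and screened
   with the operational spike criterion: a *fast* (< 400 ms) rise of the
   signal above *k·σ* of the background noise (default k = 2, σ = 1.4826 ×
   MAD of background frames, corrected for the median filter's known noise
   attenuation). Summaries are spike rates per minute and the fraction of
   active cells.
2. **Eigenvalue network synchrony.** Binarized spike trains are pairwise
   Pearson-correlated at zero lag; the spectrum of the N×N correlation
   matrix quantifies coordination, with the normalized leading eigenvalue
   λ_max/N ∈ (0, 1] as the scalar index and a circular-shift permutation
   null as the reference.
3. **Group statistics.** Kolmogorov–Smirnov normality screen, Kruskal–
   Wallis omnibus test and Dunn's post-hoc pairwise comparisons (Holm or
   Bonferroni adjustment).
4. **A per-cell-type DEG screen.** Library-size normalization + log1p,
   two-sided Wilcoxon rank-sum tests per gene, Benjamini–Hochberg FDR, and
   the significance rule `p_adj < 0.05 & |log2FC| > 0.25`; plus two-
   proportion chi-square comparisons of cell-type composition.

Everything is testable without external data: a built-in generator
simulates Poisson spike trains with a tunable shared-event synchrony knob,
renders indicator kinetics (linear rise, exponential decay, drift, noise)
into traces or disk-ROI TIFF movies, and draws negative-binomial count
matrices with planted, library-balanced log2 fold changes and a ground-truth
table.

## Worked example

Simulate one field of 50 neurons for 200 s (1000 frames at 0.2 s) with a
moderately synchronized network, run the full chain, and summarise:

```r
library(neuroflux)

cfg <- sim_config(n_neurons = 50, sync_p = 0.6, seed = 1)
sim <- simulate_spike_trains(cfg)
tm  <- render_traces(sim$spikes, cfg)
tm
#> <trace_matrix> 1000 frames x 50 ROIs, 0.2 s/frame (synthetic)

spikes <- detect_spikes(median_filter_traces(subtract_background(tm)))
spikes
#> <spike_train_set> 50 ROIs, 1000 frames (0.2 s/frame); 1460 spikes total, 50 active ROIs
spike_stats(spikes)
#> <spike_stats> 50 ROIs over 200.0 s: 8.76 spikes/min (mean), 100% active

synchrony_spectrum(cross_correlation(binarize_trains(spikes)))
#> <synchrony_result> N = 50; lambda_max = 14.963; sync index = 0.2993
```

The mean rate (8.76 spikes/min) reflects the configured private rate
(0.05 Hz = 3/min) plus shared network events joined with probability 0.6;
every cell fired at least once, so the active fraction is 1. The synchrony
index 0.299 sits far above the independence level (≈ 1/N = 0.02): the
leading eigenvalue absorbs the shared-event coordination. Comparing against
ground truth with `match_spikes(spikes, sim$spikes)` gives sensitivity
0.813 and precision 0.981 here — coincident spikes inside one
supra-threshold burst are merged by design, which lowers sensitivity at
this deliberately high event rate.

Condition comparisons and the count-matrix screen follow the same pattern;
`run_pipeline("run.yaml", "results/")` drives multi-condition,
multi-field runs (simulate → prep → detect → synchrony → Kruskal–Wallis +
Dunn; simulate counts → Wilcoxon DEG screen) from one config file and
writes CSV/JSON outputs with a digest manifest. The config schema and all
methodological choices are documented in
`vignettes/calcium-pipeline.Rmd`.

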