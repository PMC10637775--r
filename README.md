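# casync

Quantifies spontaneous network activity in calcium-imaging movies of the
developing hippocampus and seizure metrics in adult EEG recordings after a
kainic-acid challenge.

In the first postnatal week, hippocampal networks fire **synchronous
events (SEs)**: population-wide bursts of near-coincident calcium
transients. Slice physiologists summarise each movie by the SE rate, the
fraction of cells participating per SE, the total event count, the
percentage of active cells, and — at the youngest ages — the percentage of
SEs occurring in bursts. In adults, excitability is read out instead from
chronic EEG after kainic acid: latency to electrographic seizure onset,
seizure duration, and cumulative spectral band power over 90 minutes.
`casync` implements both analysis chains as tested R code, together with a
synthetic-data generator that provides ground truth for every stage.

## The methods at the core

* **Cell extraction**: PCA followed by spatiotemporal ICA (skewness
  maximisation on the μ-weighted concatenation of spatial and temporal
  components), thresholded spatial filters → ROIs → weighted-mean traces.
* **Photobleaching correction**: for each trace a cubic *support line*
  p(t) is fitted beneath the smoothed series, minimising
  Σₜ (y(t) − p(t)) subject to p(t) ≤ y(t) — a linear program solved
  exactly via its dual; the filtered series is the trace minus p(t). The
  terminal KCl window is excluded from the fit.
* **Event detection**: transients are maximal excursions of the filtered
  series at least k·SD(F₀) above the local baseline (k = 3 by default),
  with hysteresis and robust noise estimation; only cells responding
  ≥ 5 SD to the KCl depolarization are kept, and cells with events longer
  than 5 s are excluded as putative glia.
* **Synchrony**: PCA of population activity; the SE-carrying component is
  the one tracking the population event count; SE peaks are supra-threshold
  maxima of its time course; a cell participates in an SE iff it has an
  event peak within ±984 ms (= ±3 frames at 0.328 s/frame); SEs whose
  connecting PC segment never returns to baseline chain into bursts.
* **EEG**: 10 s epochs, Hann-periodogram band power (δ/θ/α/σ/β/γ),
  90-min cumulative power, and an EEG-only onset call — the first 10 s
  window with a twofold increase in both RMS amplitude and median
  frequency over baseline, sustained 10 s.
* **Statistics**: one-sample ROUT outlier screening (Q = 1 %) of per-movie
  counts, then linear mixed models `value ~ group + (1 | animal)` with
  Dunnett-adjusted contrasts versus control (lmerTest + emmeans).

## Worked example

```r
library(casync)

## a 100-cell, ~5-minute movie with known ground truth
sim <- simulate_traces(trace_sim_params(n_cells = 100, seed = 42))
an  <- analyze_traces(sim$traces, kcl_window = sim$truth$kcl_window)
an
#> <movie_analysis> 304 s, 85 retained cells | 7 SEs (1.38/min), 583 events,
#>   62.0% cells/SE, 100.0% active, 28.6% SEs in bursts
length(sim$truth$se_frames)   # generator truth
#> [1] 7
```

The analysis retained 85 of 100 cells (the generator planted 10 %
non-viable and 5 % glia-like cells; both filters recovered the truth
masks exactly here), found all 7 true SEs with a mean participation of
62 % — the generator draws participation around 60 % — and counted 583
calcium events, 211 of them asynchronous.

```r
## EEG: seizure starts 500 s after injection (600 s into the recording)
eeg <- simulate_eeg(eeg_sim_params(duration_s = 1000, seizure_onset_s = 600,
                                   seizure_offset_s = 900, seizure_gain = 3,
                                   injection_time_s = 100, seed = 42))
detect_onset(eeg)
#> <seizure_call> onset 498.5 s, offset 800.0 s, duration 301.5 s
#>   (EEG-only twofold amplitude+frequency; offset 1.5x/30s (reporting convention))
```

Onset is called 1.5 s early and the 300 s duration is recovered within
1.5 s.

```r
## group comparison: movies nested in animals, outliers screened first
set.seed(42)
d <- data.frame(value  = c(rnorm(40, 10, 2), rnorm(40, 13, 2)),
                group  = rep(c("ctrl", "treat"), each = 40),
                animal = rep(1:20, each = 4))
keep <- !rout_outliers(d$value, Q = 0.01)$mask
fit_group_lmm(d[keep, ], control = "ctrl")
#> <group_comparison> mixed model value ~ group + (1|animal)
#>   variance components: animal 0.1297, residual 4.547
#>      contrast estimate        SE df lower.CL upper.CL        p_raw        p_adj
#>  treat - ctrl 3.238762 0.5032793 18 2.181411 4.296112 4.678744e-06 4.678744e-06
```

The estimated treat − ctrl difference (3.24 ± 0.50) covers the simulated
difference of 3; with a single contrast the Dunnett adjustment leaves the
p-value unchanged.

## Documentation

Every exported function carries roxygen documentation;
`vignettes/network-synchrony-methods.Rmd` explains the models, parameter
defaults, numerical choices, what the synthetic generator does and does
not emulate, and known limitations.
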