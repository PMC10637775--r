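---
title: "Quantifying developing-network synchrony and seizure EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying developing-network synchrony and seizure EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casync)
```

## The scientific problem

In the first postnatal week, hippocampal networks generate spontaneous
*synchronous events* (SEs): population-wide bursts in which a large
fraction of cells fire near-coincident calcium transients. The rate of
SEs, the fraction of participating cells, the overall event count and the
tendency of SEs to cluster into bursts are the standard readouts of
immature network excitability in acute-slice calcium imaging (Fluo-4,
~0.328 s/frame, with a terminal KCl depolarization certifying cell
viability). In adults, network excitability is probed instead with a
kainic-acid challenge under chronic EEG: time to electrographic seizure
onset, seizure duration, and cumulative spectral band power over the
90 minutes after injection.

`casync` implements both analysis chains as tested, reusable code, plus a
synthetic-data generator that provides ground truth for every stage. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the validation does and does not demonstrate.

## Calcium pipeline

### Cell extraction (`pca_ica_segment`)

Movies (assumed motion-corrected) are decomposed by PCA on the
pixels-by-frames matrix, followed by spatiotemporal ICA: the whitened
spatial and temporal principal components are concatenated with weight
`mu` (default 0.5) and rotated by a fixed-point iteration that maximises
skewness -- cells are sparse bright blobs, so their filters are strongly
right-skewed. Each independent component's spatial filter is z-scored,
thresholded (default 3 SD), split into connected components of at least
`min_roi_pixels` (default 5) pixels, and de-duplicated at IoU 0.5. Traces
are weighted ROI means of the raw movie, so extraction is linear in the
movie. The number of retained components is a parameter; ~1.5x the
expected cell count works well. A structureless movie produces zero ROIs,
not an error.

Manual curation of candidate cells is replaced by these programmatic
filters so that results are reproducible end to end.

### Photobleaching correction: the cubic support line

Each trace is smoothed by a zero-phase 2nd-order Butterworth low-pass
(default cutoff 0.5 Hz; DC must survive because the envelope is what we
are fitting; odd-reflection padding suppresses the filter's edge
transients, which would otherwise anchor the fit). The *support line* is
the cubic lying entirely beneath the smoothed trace that minimises the
total gap -- an L1 lower-envelope fit, which is a linear program in the 4
cubic coefficients. We solve the dual (4 equality constraints, one
multiplier per frame) with `boot::simplex`, recovering the cubic from the
at-most-4 active frames; a primal fallback covers rank-deficient active
sets. On random series the solution matches a brute-force vertex
enumeration to 1e-6 (tested), and the fit is exactly equivariant to adding
any cubic, which is what makes event detection drift-invariant. The
terminal KCl window is excluded from the fit. Only the L1 objective is
offered; it is convex, admits an exact small-scale oracle, and needs no
quadratic-programming machinery.

### Event detection

The filtered series is the raw trace minus the support line. Two
estimates accompany it:

* **F0 level**: the support line is a *lower* envelope, so the filtered
  series keeps a small positive offset that wanders slowly (the envelope
  touches only a few minima). The baseline level is therefore a 30 s
  running median -- long relative to any transient, including slow glial
  waves, short relative to the envelope misfit.
* **F0 SD**: 1.4826 x the median absolute *negative* deviation from the
  local level. Transients deflect the trace only upward, so the negative
  flank is pure noise even when events occupy a third of the frames; a
  plain MAD is inflated ~40% at that density.

Events are detected with a two-threshold (hysteresis) rule: extent at
`k - 1` SD above the local level, existence requiring a peak of at least
`k` SD (default `k = 3`, the standard multiple of the F0 SD) and at least
2 frames. Sub-threshold gaps of up to 2 frames are closed; a closed run is
re-split only at interior valleys that fall back below the boundary, so
two bridged transients get separate peaks while a noisy glial plateau
never splits. Peaks are localised on a 3-point weighted average (ties go
to the earliest frame); the peak frame is the event's timestamp
everywhere downstream. At the 0.328 s frame period these choices give
precision and recall above 0.95 for 6-SD events, and adding an arbitrary
cubic drift moves no peak by more than one frame (both tested).

### Viability and glia filters

Cells are retained only if their detrended trace rises at least 5 SD (the
default) above the local pre-window baseline during the KCl challenge.
The reference is the median of the ~10 s before the window because the
support line is extrapolated through the excluded window and its cubic
tail cannot be trusted there. Cells with any event strictly longer than
5 s are excluded as putative glia (a 5.0 s event is kept). All population
denominators downstream use only retained cells.

### Synchrony analysis

PCA runs on the detrended traces of retained cells (not on the binary
raster): the PC time course then has a real amplitude baseline, which the
burst rule needs. Each component is sign-oriented to non-negative
skewness. The SE-carrying component is chosen automatically as the one --
among the first 3 -- whose time course best correlates with the
population event-count series convolved with a causal exponential
(1 s, the transient decay): the PC trace is a calcium signal, so the
counts must carry the same temporal signature before correlating.
Confidence is that correlation; values around 0.9 are typical for genuine
SE movies, while the chance level under purely asynchronous activity is
~0.35-0.4 (the shared smoothing kernel keeps it well above zero), so
selections below 0.5 are flagged low-confidence.

SE peaks are local maxima of the PC trace at least 3 robust SDs above its
median, subject to two guards with defaults chosen from the failure modes
they prevent: a shoulder-merge rule (consecutive maxima are distinct SEs
only if the trace between them drops at least 2 robust SDs below the
smaller peak -- decay echoes 1.5-2.5 s after a real SE otherwise count
twice, while genuine burst members are far more prominent than this), and
a minimum participation of 10% of retained cells (supra-threshold chance
coincidences of asynchronous events carry only 1-5%).

A cell participates in an SE iff it has an event peak within
`round(0.984 / frame_period)` frames of the SE peak -- exactly +/-3
frames at 0.328 s, i.e. the 984 ms window. Every event is synchronous or
asynchronous, never both, and the two counts always sum to the total
(tested as an invariant). Bursts chain consecutive SEs whose connecting
PC segment never returns to baseline, operationalised as staying above
the 10th percentile of the PC trace plus 0.5 robust SD; maximal chains of
at least two SEs are bursts, and the reported percentage is the share of
SEs inside bursts.

Per-movie summaries collect: SE count and rate per minute, total events
of retained cells (an asynchronous-only count is also emitted), mean SE
participation in percent, percent of active cells, and percent of SEs in
bursts.

## EEG pipeline

Recordings are split into consecutive 10 s epochs from the injection
time; trailing samples are dropped and epochs overlapping the artifact
mask (movement/grooming) are excluded. Band power uses a Hann-windowed
one-sided periodogram normalised so a pure sinusoid of amplitude A
contributes A^2/2; band edges default to delta 0.5-4, theta 4-8, alpha
8-12, sigma 12-16, beta 16-24, gamma 24-80 Hz (half-open intervals,
fully overridable -- the conventional band set; the edges themselves are a
package default). Band powers partition the total over the union range
exactly (Parseval; tested to 1e-6 relative). Cumulative power sums
included epochs over the 90-min reporting period. Because "total power
across all frequencies (24-80 Hz)" is ambiguous as printed, both the
union-range total and the 24-80 Hz total are emitted.

Seizure onset is called EEG-only (behavioral video confirmation is out of
scope): the first sliding 10 s window in which RMS amplitude is at least
twice the baseline RMS *and* the median frequency (50% spectral edge over
1-80 Hz) is at least twice its baseline value, sustained 10 s. The median
frequency was chosen over higher spectral edges because it is pinned by
the delta-dominated background (~2 Hz) and rises several-fold during
rhythmic spiking, whereas the 75% edge wanders enough across noise
realizations to straddle the twofold line. The coarse onset is refined by
a 2 s sub-window RMS scan, removing the ~7 s lead a 10 s window otherwise
produces. The offset rule -- RMS back below 1.5x baseline for 30 s -- is a
reporting convention invented here (flagged as such in the output), since
a duration must end somewhere. The whole criterion is ratio-based and
therefore invariant to global amplitude rescaling (tested).

## Group statistics

Per-movie counts are screened with a one-sample ROUT at Q = 1%: robust
center = median, robust SD = the 68.27th percentile of absolute residuals
with the n/(n-1) small-sample correction, two-sided t ratios (df = n-1),
and a Benjamini-Hochberg-style step over at most the 30% most extreme
points. This adaptation is the package's normative definition and is what
the tests check: it flags the planted outlier in the worked sample
{1,2,3,2,1,2,3,100}, is affine-equivariant, and has an any-flag rate of
~1-2% on clean Gaussian samples.

Group comparisons fit `value ~ group + (1 | animal)` by REML with
Satterthwaite degrees of freedom (lmerTest) and compare each group to the
control with Dunnett-type contrasts via emmeans' multivariate-t
adjustment (seeded quasi-Monte-Carlo; adjusted p-values are clamped to be
at least the raw ones, guarding against QMC jitter). Singular fits are
reported, not hidden; with one observation per animal the estimates
reduce to the fixed-effects group means.

## The synthetic generator: what it emulates, and what not

`simulate_traces()` builds traces as cubic bleaching baseline + transient
kernels + KCl response + i.i.d. Gaussian noise. Defaults encode the
emulated study conditions: ~5 min of analysed activity at 0.328 s/frame,
SE seeds as a Poisson process at 2/min, participation drawn per SE from
N(0.6, 0.1) over viable non-glia cells with +/-1-frame spike jitter,
asynchronous events at 0.5/cell/min, transient kernel rise 0.05 s / decay
1 s, amplitudes ~6 noise SD, 10% non-viable (silent, KCl-unresponsive)
and 5% glia-like cells. Glial events are large (10 SD) and slow (decay =
`glia_event_duration_s`, default 6 s) so the >5 s exclusion rule applies
to them, and every glia cell carries at least one -- a glia cell with no
events would be undetectable in principle. With `burst_prob > 0` an SE
seed expands into a geometric-size burst at 2 s spacing: short enough
that the population trace stays far from baseline between members, long
enough that members remain distinct peaks given the spike jitter the
generator itself models (at 1 s spacing they fuse into a single monotone
rise and are not separate SEs even in principle). Truth burst membership
is defined by inter-peak gaps of at most 1.5x the burst spacing, which is
what the chained seeds produce. Generator rates are chosen for
testability; control-condition SE magnitudes are not reported numerically
in the source material, so no attempt is made to mimic specific figure
values. The bleaching baseline is an exact cubic, so the support-line
assumption is exactly satisfiable in the default fixture; real bleaching
is only approximately cubic.

`render_movie()` places disc ROIs on a shuffled grid and sets their
pixels to the trace values over a constant background plus pixel noise,
so ROI means reproduce the traces exactly at zero noise.

`simulate_eeg()` is a 1/f^2 background (the standard resting-EEG slope;
with slope 1 the spectral mass sits so high that a twofold frequency
increase is impossible within the analysis range) band-limited below
1 Hz -- emulating the 1-200 Hz recording band and keeping window RMS
stationary -- plus sinusoidal band components, and a seizure segment that
multiplies the signal by `seizure_gain` and superimposes rhythmic sharp
biphasic spikes (8/s), emulating high-amplitude electrographic discharge.

What the generator does **not** emulate: real ROI shapes and overlaps,
motion, non-Gaussian shot noise, GABA-dependent network dynamics (no
conductances), spike inference, wave propagation, EKG contamination, or
behavioral artifacts. Passing the validation therefore demonstrates that
the algorithms recover the statistical structure they assume -- not that
they are robust to every pathology of real recordings; the KCl and glia
filters, for example, are only as good as the assumption that viability
shows as a >=5 SD depolarization response and glia as >5 s events.

## Numerical choices and degenerate inputs

* Support-line LP: series are shifted so constraints are positive and the
  basis is evaluated on normalized time in [-1, 1] for conditioning; the
  raw frame-basis coefficients are recovered by exact polynomial
  reparameterization. Constant series, exact cubics and short series
  (>= 8 included frames required) are all exact.
* Ties in event peak argmax resolve to the earliest frame; plateau maxima
  of the PC trace resolve to their first frame.
* Zero-variance movies and traces yield empty results or explicit errors
  (`population_pca` refuses a zero-variance matrix; `detect_events`
  requires a positive baseline SD).
* Determinism: every generator is seeded and bit-identical under the same
  seed; the Dunnett multivariate-t adjustment is seeded as well.
* Validation problem sizes (chosen to exercise the study conditions at
  laptop scale): 100-cell, 5-min movies for pipeline recovery (20 seeds);
  a 10-cell rendered movie for extraction; 50 seeded seizures of ~17 min
  at 500 Hz for onset statistics; 1000 replicates for ROUT calibration
  and 100 for mixed-model coverage.

## Known limitations

* Burst percentages are compared against generator truth defined by gap
  chaining; for SE pairs with gaps of 3-4.5 s the "did not return to
  baseline" rule and the truth definition can legitimately disagree (the
  population trace physically cannot return within ~3 s of a large SE),
  so per-movie burst percentages scatter around truth and only the
  regime mean is tight.
* The support line assumes bleaching is cubic over the analysed window;
  strong non-polynomial drift (e.g. perfusion steps) will leak into the
  filtered series.
* `analyze_traces` crops all population statistics to the pre-KCl window;
  movies without a KCl challenge are analysed whole, with the viability
  filter skipped.
* EDF and HDF5 I/O are not provided; EEG is read from two-column
  delimited text and traces from CSV (plus TIFF movies).
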