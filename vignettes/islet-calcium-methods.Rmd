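---
title: "Methods: beta-cell Ca2+ event kinetics, networks, and organelle contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-cell Ca2+ event kinetics, networks, and organelle contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `isletca`. It is the place to look when you need to know
*why* a stage behaves the way it does, what its tunable parameters mean,
and what the synthetic-data validation does and does not demonstrate.

## The analysis chain

Fast confocal recordings of islets in pancreatic tissue slices produce XYT
stacks (nominally 20 Hz, 256 x 256 px) in which beta cells exhibit
oscillatory cytosolic Ca2+ transients. The chain is:

1. **Statistical image** — per pixel, temporal mean plus a high temporal
   percentile of intensity. Pixels that carry transients have a heavy upper
   tail, so they outscore equally bright but inactive pixels; the resulting
   image separates active cells from background.
2. **ROI segmentation** — Otsu threshold on the statistical image,
   distance-transform watershed to split touching cells, 8-connected
   components, area gate.
3. **Trace extraction** — per-ROI mean intensity per frame.
4. **De-bleaching (F/F0)** — division by a fitted slowly varying baseline.
5. **Event detection** — multi-timescale band-pass filtering (dyadic scales
   1–256 s), z-scoring against a robust noise floor, threshold z > 4,
   cross-scale merging; each event is measured by its full width at half
   maximum (FWHM, "halfwidth") and its midtime (midpoint of the FWHM
   interval).
6. **Filters** — ROIs with fewer than 5 events over the whole recording are
   discarded (low-activity cells), then events are restricted to the
   dominant fast band, halfwidth 1–10 s inclusive.
7. **Summaries** — events are assigned to protocol conditions (glucose,
   epinephrine, acetylcholine intervals), and per-condition kernel density
   estimates, medians and two-sample tests are computed. Inter-event
   intervals (IEI) are midtime differences of consecutive events within one
   ROI.
8. **Dose–response** — four-parameter logistic fits of activity readouts
   against agonist concentration.
9. **Functional networks** — thresholded zero-lag correlation graphs per
   condition, summarized by mean node degree, average clustering and global
   efficiency.

A separate branch quantifies mitochondria–ER contact sites and ER
surface-area-to-volume ratios from electron-microscopy segmentation masks.

## Statistical image and segmentation

The upper percentile defaults to the 99th (the value is exposed as
`upper_percentile`; any 50 < p <= 100 is accepted) and uses linear
interpolation between order statistics (R quantile type 7), so a single hot
frame cannot dominate. Which thresholding and splitting algorithm to use is
genuinely open; we chose Otsu + distance-transform watershed because both
are standard, deterministic and parameter-light, and because the package's
validation criterion is ground-truth overlap (Jaccard against planted
cells), not any specific algorithm. ROI labels are renumbered in row-major
centroid order so runs are reproducible. Manual ROI curation is supported
by passing a user-supplied label image to `extract_traces()` instead of a
`segment_rois()` result.

Area gates default to 30–2000 px, sized for beta cells imaged at 256 x 256;
both are parameters, as is a light Gaussian pre-smoothing (`smooth_px = 1`)
that stabilizes Otsu on noisy statistical images.

## De-bleaching

`debleach()` estimates a running low-quantile envelope (10% quantile in
30-s windows) which transients barely perturb, fits a
constant-plus-exponential to that envelope (`method = "exponential"`,
Levenberg–Marquardt), divides, and rescales so the output's median is
exactly 1. The rescaling removes the systematic offset between a low
quantile of the noise and the true baseline. For baselines that are not
exponential, `method = "quantile"` uses the smoothed envelope directly.
On a transient-free exponential decay (tau = 300 s) the residual deviation
from 1.0 is below 1%, and a planted transient's relative amplitude is
preserved within 5% (both asserted in the test suite).

## Event detection

Each dyadic timescale `s` in 1–256 s is isolated by a difference of
Gaussian smoothings with sigma = s/2.355 and 2s/2.355 (so the narrow kernel
matches a pulse of FWHM `s`). Scales longer than half the trace are skipped
with a warning. Detections are excursions of the standardized band above
`z_thresh = 4` (strict).

**Noise floor.** A natural first choice, the MAD of the band-passed trace,
fails in exactly the regime this package targets: on dense trains (median
IEI near 12 s, the fast phenotype) transients occupy a large fraction of
the recording, the band MAD measures the events rather than the noise, and
recall collapses to roughly 60%. We therefore estimate the white-noise
level from the first difference of the trace — transients are slow relative
to the 50-ms frame interval, so the difference is noise-dominated even on
dense traces — as `mad(diff(x)) / sqrt(2)`, and propagate it through each
band-pass filter's known l2 gain. One reweighting step (excluding samples
beyond 3 of these z-units, then taking the MAD of the remainder, never
below the propagated floor) captures signal-induced filter ripple that pure
white-noise propagation misses. With this floor, recall on planted trains
(amplitude 8 sigma, FWHM 2–6 s) is 100% and false positives on pure noise
are about 0.3 per 600-s trace at z > 4.

**FWHM measurement.** The halfwidth is measured on the de-bleached trace,
not the filtered band. Half-maximum crossings are located by linear
interpolation on a lightly smoothed copy (sigma = scale/8 samples) so a
single noise dip near the half level cannot truncate the walk; the
smoothing's quadratic FWHM widening is then removed
(`fw = sqrt(fw_meas^2 - blur^2)`), which is exact for Gaussian pulses. A
measurement at or below the blur itself is discarded as unresolvable at
that scale. The local baseline is the 25% quantile of a window around the
peak, excluding the event; the window is rescaled to the measured width in
a second pass, because a window proportional to the *detection* scale
biases wide events detected at small scales. The low quantile (rather than
the median) keeps neighbouring events on dense trains from inflating the
baseline.

**Cross-scale merging.** Detections are merged finest scale first: a
coarser detection is kept only where no accepted finer detection's FWHM
interval overlaps it. Selecting instead the detection of maximal z across
scales systematically favours coarse scales (their bands carry less noise),
and one coarse blob then swallows two resolved fast events — on planted
dense trains this inflated the measured median IEI by ~60%. With
finest-first merging, event counts on planted trains are recovered exactly
in the validation suite.

The detection threshold (z > 4), scale range (1–256 s), activity filter
(>= 5 events per ROI, counted before band filtering) and halfwidth band
(1–10 s inclusive) are fixed protocol constants of the analysis; all are
exposed as parameters.

## Summaries, KDEs, tests

Kernel density estimates use a Gaussian kernel with bandwidth
`factor * sd(values)`; the factor defaults to 0.2, the scalar
bandwidth-factor convention in which the factor replaces the rule-of-thumb
multiplier. Curves are renormalized to integrate to 1 on their grid, so
differences of two curves integrate to 0.

Inter-event intervals that straddle a condition boundary are assigned to
the earlier event's condition and discarded when the two events lie in
different conditions; this avoids artifactual long intervals at solution
changes. Pooling across ROIs is the default; `per_roi = TRUE` computes
medians of per-ROI medians instead (both modes exist because either pooling
convention is defensible). Medians of even-sized samples are the mean of
the central pair. No multiple-testing correction is applied; p-values are
reported raw.

The Mann–Whitney U test enumerates all group labelings exactly (average
ranks for ties) whenever `choose(n_a + n_b, n_a) <= 50000`, with the
two-sided p as `2 * min(P(U <= u), P(U >= u))` capped at 1, and falls back
to the normal approximation with continuity correction for larger samples.
The t test is Student's (pooled variance); the KS test is the asymptotic
two-sample test. These conventions are asserted against brute-force
permutation oracles in the tests.

## Dose–response

The four-parameter logistic is
`response = bottom + (top - bottom) / (1 + (ec50/conc)^hill)`.
Fits run in log-concentration space (the natural scale for ramps spanning
decades, e.g. 0.1–100 nM epinephrine) with data-driven starts (bottom/top
from the response extremes, EC50 at the geometric-mean concentration,
Hill = ±1 by response direction) and unweighted least squares. The fitted
parameters are canonicalized to `top > bottom` with the Hill sign carrying
direction, which removes the (bottom, top, hill) <-> (top, bottom, -hill)
degeneracy. Noiseless tables are recovered to 1e-4 relative error; with 2%
noise on 7 concentrations the median EC50 relative error is about 10%,
which is the information limit of that design rather than an optimizer
artifact.

## Functional networks

Correlations are zero-lag Pearson on de-bleached traces restricted to the
condition's time window ("0.7 explains ~50% of the variance" only makes
sense for a correlation coefficient, which is why the default is zero-lag
rather than a lagged cross-correlogram; a max-over-lags option exists).
Edges are inclusive at the threshold (correlation >= 0.7). Metrics follow
the standard conventions: mean degree 2|E|/K; average local clustering with
0 for nodes of degree < 2; global efficiency as the mean inverse shortest
path over distinct pairs, with disconnected pairs contributing 0 — the only
convention under which efficiency remains defined for the largely
disconnected networks of the fast/weakly-coupled phenotype. All three are
verified against a brute-force BFS/triangle oracle.

## Mitochondria–ER contacts

A mitochondrion perimeter pixel (>= 1 of its 4-neighbours outside the mask)
is in contact when any ER pixel lies within 10 nm, measured centre to
centre (2 px at the 5 nm/px SEM resolution, inclusive at exactly 10 nm).
Contact sites are 8-connected runs of in-contact perimeter pixels at least
10 nm (2 px) long; a mitochondrion is ER-coupled when strictly more than 5%
of its perimeter pixels belong to qualifying sites. Distances elsewhere in
the module (nearest-distance profiles) use the same centre-to-centre
convention; directly adjacent pixels are therefore 5 nm apart, and mask
disjointness forbids shared pixels, not touching.

ER surface areas from 3-D masks are reported two ways: exposed-face
counting (`"faces"`), which is exact for the voxel object itself but
overestimates smooth membranes by up to 3/2; and a smooth-surface estimator
(`"smoothed"`) that blurs the binary object with a small Gaussian
(sigma = 1.5 voxels by default: small against object radii, large against
the grid) and integrates the gradient magnitude (the coarea identity),
which converges to the area of the underlying smooth interface. On a
digitized ball of radius 20 voxels the smoothed estimate is within about
0.5% of the continuum value 3/r. Volumes are voxel counts times the voxel
volume; objects are 6-connected components.

## The synthetic-data generators

The study's raw recordings and EM volumes are not deposited, so every
stage is validated against generators with analytic ground truth.

**Traces.** Each cell fires a renewal process with log-normal inter-event
intervals (strictly positive and heavy-tailed, like the observed interval
distributions) and log-normal FWHM; transients are Gaussian pulses
parameterized directly by FWHM (`FWHM = 2.355 sigma_t`), so the detector's
halfwidth accuracy is assertable in closed form; an asymmetric
rise/decay kernel is available but not the default. Traces are
`baseline * bleach(t) * (1 + sum of transients) + Gaussian noise`, with
exponential photobleaching. Defaults: 20 Hz, baseline 100, amplitude
8 sigma, halfwidth median 4.0 s (dispersion 0.3) and IEI median 30 s
(dispersion 0.4) — a slow/sparse glucose-stimulated regime in the middle of
the condition medians the analysis is designed for (halfwidths ~2.5–5.5 s,
IEIs ~12–44 s); the fast/frequent regime used in validation plants 2.8 s /
12 s. Per-event amplitude statistics are not reported for the real
recordings, so the 8-sigma default is chosen for detectability, not
fidelity.

**Coupling.** A shared renewal "islet clock" per coupled component
co-fires in *all* members with the stated probability `p` (shared
kinetics); each cell keeps its own events with probability `1 - p`. This
all-or-none design makes the pairwise correlation scale like `p` itself.
The alternative — each cell adopting clock events independently — caps
pair correlation near `p^2` (~0.72 at p = 0.9), right at the 0.7 network
threshold, which would make coupling-to-connectivity validation depend on
the noise realization rather than on the coupling strength. No gap-junction
biophysics is simulated.

**Movies.** Cells are non-overlapping disks whose pixels carry the cell's
clean trace plus independent per-pixel Gaussian noise (default sd 10 at
baseline 100, i.e. pixel SNR well below trace SNR until averaged over a
cell's ~80 px); background pixels carry a constant level plus noise, and
negatives are clipped at zero. No point-spread function or motion is
simulated: segmentation validation shows the pipeline recovers disks from
realistic noise, not that it tolerates optical blur or drift.

**Organelle masks.** Mitochondria are rectangles on well-separated grid
slots; ER rectangles attach at known pixel gaps (1–3 px) and facing
lengths, so perimeter, contact length and coupled state follow in closed
form from the layout, independently of the pixel-scanning measurement.
Gaps of at least one empty column keep the analytic truth exact (no
diagonal-contact corner cases).

**Problem sizes.** Validation uses 600-s single-trace recordings (10
seeds) for detector accuracy, 48 x 48 px six-cell movies (600 s, 10 seeds
per phenotype) for the end-to-end medians, 10-cell populations for the
coupling contrast, 50 random layouts (9 mitochondria each) for contact
classification, and a radius-20 digitized ball for the smooth-surface
check. These sizes give stable medians (hundreds of events per phenotype
run) while keeping the full validation suite in the minutes range on one
CPU.

**What passing does not show.** The generators share the analysis's own
shape assumptions (Gaussian pulses, white noise, exponential bleaching,
disk-shaped cells, rectangular organelles). Passing therefore demonstrates
internal correctness and calibration of every documented rule, not
robustness to asymmetric transient shapes, correlated noise, drifting
baselines beyond exponential, irregular cell shapes, or segmentation-model
errors in the EM masks. The printed medians of the original recordings are
not reproducible from this package because those raw data are not
deposited; the validation targets are planted parameters instead.

## Degenerate inputs and tie-breaks

* Constant traces de-bleach to exactly 1; constant statistical images yield
  zero ROIs with a message, not an error.
* Zero-variance traces inside a correlation window get zero rows/columns
  and a warning; their nodes simply remain isolated.
* A z-run whose local excursion has no positive height, or whose measured
  width does not exceed the measurement blur, yields no event.
* `filter_rois` keeps an ROI with exactly `min_events` events; the
  halfwidth band is inclusive at both edges; coupling is strict at the 5%
  perimeter fraction; contact proximity is inclusive at 10 nm.
* ROI labels, mitochondria labels and site labels are ordered
  deterministically (row-major centroids), so identical inputs give
  byte-identical outputs.
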