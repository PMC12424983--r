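# isletca

Analysis of beta-cell cytosolic Ca²⁺ dynamics in pancreatic tissue-slice
imaging, for physiologists quantifying how islet beta cells respond to
glucose, epinephrine and acetylcholine: from raw XYT fluorescence stacks to
per-cell Ca²⁺ event kinetics, per-condition statistics, dose–response fits
and functional beta-cell networks — plus quantification of mitochondria–ER
contact sites and ER surface-area-to-volume ratios from electron-microscopy
segmentation masks.

## What it computes

**Imaging branch.** A recording (nominally 20 Hz, 256 × 256 px) is reduced
to a *statistical image* (per-pixel temporal mean + 99th temporal
percentile), segmented into ROIs (Otsu threshold, distance-transform
watershed, area gate), and each ROI's trace is de-bleached (F/F₀ against a
fitted slowly-varying baseline). Oscillatory events are detected across
dyadic timescales 1–256 s by band-pass filtering and z-scoring against a
robust noise floor, keeping excursions with z > 4. Each event is measured by
its halfwidth — the full width at half maximum (FWHM) of the de-bleached
transient — and its midtime; inter-event intervals (IEI) are midtime
differences of consecutive events within an ROI. ROIs with fewer than 5
events are discarded and events are restricted to the dominant 1–10 s band.
Per protocol condition the package reports kernel-density estimates
(Gaussian kernel, bandwidth factor 0.2), medians, and Mann–Whitney U /
Student's t / Kolmogorov–Smirnov comparisons.

**Pharmacology.** Activity readouts over an agonist ramp are fitted with the
four-parameter logistic

    response = bottom + (top − bottom) / (1 + (EC50 / conc)^hill)

in log-concentration space, reporting bottom, top, EC₅₀ and the Hill
coefficient.

**Networks.** Per condition, ROIs become nodes of an unweighted undirected
graph with an edge wherever the zero-lag Pearson correlation of the
de-bleached traces is ≥ 0.7; the package reports mean node degree, average
clustering, and global efficiency (disconnected pairs contribute 0).

**Organelle branch.** From 2-D mitochondria/ER masks (5 nm/px SEM
convention): contact sites are ≥ 10 nm runs of mitochondrion perimeter
pixels lying within 10 nm of ER; a mitochondrion is ER-coupled when > 5% of
its perimeter is in qualifying sites. From 3-D ER masks: per-object surface
area (exposed-face counting, or a smooth-surface estimator), volume, and
SA/V.

Because raw recordings for this kind of study are rarely deposited, the
package ships ground-truthed synthetic generators (coupled oscillatory trace
populations, islet movies, dose–response tables, organelle mask layouts)
that validate every stage against planted truth.

## Worked example

Simulate a fast/frequent six-cell islet movie (planted halfwidth median
2.8 s, IEI median 12 s), run the imaging chain, and summarize:

```r
library(isletca)

spec <- trace_population_spec(
  n_cells = 6, duration_s = 600, rate_hz = 20,
  halfwidth_dist = c(2.8, 0.25),   # median FWHM 2.8 s
  iei_dist = c(12, 0.35),          # median inter-event interval 12 s
  amplitude_snr = 8, bleach_tau_s = 900, seed = 42)
layout <- cell_layout(expand.grid(row = c(12, 36), col = c(8, 24, 40))[, 1:2],
                      radius_px = 5)
sim <- simulate_movie(spec, layout, dim_px = c(48, 48))

rois   <- segment_rois(statistical_image(sim$movie))
traces <- extract_traces(sim$movie, rois)
events <- band_filter_events(filter_rois(detect_events_set(traces)))
timeline <- protocol_timeline(0, 600, "8 mM glucose")
condition_medians(assign_condition(events, timeline))
#>      condition median_halfwidth_s median_iei_s n_events n_iei
#> 1 8 mM glucose           2.707271     12.74197      271   265

net <- build_network(correlation_matrix(traces), threshold = 0.7)
network_metrics(net)
#> $mean_node_degree
#> [1] 0
#> $average_clustering
#> [1] 0
#> $mean_efficiency
#> [1] 0
```

The recovered medians (2.71 s, 12.7 s) sit within a few percent of the
planted parameters (2.8 s, 12 s), and the uncoupled population correctly
yields an edgeless network at the 0.7 threshold: each detected event table
row carries `roi_id`, `onset_s`, `midtime_s`, `halfwidth_s`, `peak_z` and
the detection `scale_s`. `run_pipeline()` wraps the same chain behind a
single config (R list, YAML or JSON) and writes every intermediate table
plus a provenance manifest.

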