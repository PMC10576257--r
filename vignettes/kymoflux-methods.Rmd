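---
title: "Quantifying axonal cargo transport with kymoflux: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axonal cargo transport with kymoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoflux)
```

## The measurement problem

Live-cell recordings of axons show vesicular cargo — lysosomes, late
endosomes, mitochondria — moving bidirectionally along the axon shaft.
The standard quantification collapses each time-lapse movie onto the axon's
one-dimensional geometry as a *kymograph* (time × position), traces each
punctum through time, and segments every trace into *directed runs*, *pauses*
and a *motile / stationary* label. From the segmented traces a movie-level
summary is computed: per-direction flux, mean run speed, mean run length,
mean pause duration, event counts, directionality, percent stationary cargo,
and linear cargo density. Treatment groups are then compared per parameter.

kymoflux implements this pipeline end to end, together with two companion
assays (two-channel puncta colocalization for lysosomal-rupture readouts,
and field-of-view intensity quantification) and the group statistics. Because
raw recordings of this kind are rarely deposited, the package also ships a
stochastic simulator whose ground truth lets every stage be validated — each
green test certifies a property of the code on data whose answer is known, not
agreement with any particular biological dataset.

## Segmentation rules

All rules live in `run_rule_config()` and operate in physical units:

* **Directed run.** A maximal unidirectional stretch of a trace qualifies as
  a directed run if its displacement is at least `run_threshold` (default
  **5 µm**). The cutoff is chosen to dominate diffusion: a freely diffusing
  vesicle with `D = 0.01 µm²/s` moves only `sqrt(2 D t) = 1 µm` RMS over a
  `t = 50 s` horizon (`diffusion_bound()`), so a 5 µm excursion cannot be
  mistaken Brownian motion. The constructor enforces
  `run_threshold >= diffusion_bound(D, t)` as an invariant.
* **Run termination.** A run ends where the particle remains at the same
  position — per-frame movement within `same_position_tol` — for at least
  `pause_min_frames` (default **4**) consecutive frames, or where it reverses
  direction. "Same position" is never exact on pixelated data; the default
  tolerance is 2 pixels at the 630× calibration (1 pixel = 0.160508 µm,
  so 0.321 µm), i.e. within localization jitter, and is configurable.
* **Reversals.** Each maximal unidirectional stretch is a separate run
  candidate, matching per-event kymograph tracing practice. The cut between
  two opposite stretches is placed at the extremal position inside the
  sub-tolerance window around the turn; this convention makes segmentation
  exactly invariant to time reversal (up to direction relabeling), which the
  test suite asserts on randomized traces.
* **Run duration and speed.** Duration counts only frames with
  supra-tolerance movement, so brief (< `pause_min_frames`) stalls inside a
  run do not dilute its mean speed; speed = displacement / duration.
* **Stationary cargo.** A trace is stationary if its whole-movie positional
  excursion (max − min) is below `stationary_threshold` (default **5 µm**);
  traces spanning less than half the movie are excluded as unclassifiable.
  Note the two 5 µm rules measure different things: the run rule applies per
  candidate stretch, the stationary rule to the whole movie.
* **Flux.** Per direction, the sum of directed-run displacements divided by
  axon length and movie duration, `sum(d_i) / (l · t)`, with `t` in minutes:
  µm of cargo travel per µm of axon per minute.
* **Density.** (directed runs + stationary objects) / kymograph length.
* **Pause duration** is reported only for traces that produced at least one
  directed run, so the movie-long "stall" of a stationary vesicle does not
  swamp the statistic.

Two independent implementations of the stall search exist: a linear scan and
an exhaustive enumerator of all maximal stall windows (`brute_force = TRUE`).
They are proven equal on randomized batteries; the fast scan is the default.

## Kymographs and tracking

`build_kymograph()` resamples the axon path at 1-pixel arc steps and takes,
per time point, the maximum intensity over `sampling_width` pixels
perpendicular to the path (maximum projection suits punctate cargo on a dim
background). Columns are sampled at arc midpoints, which makes reversing the
path plus flipping the soma flag an exact mirror of the kymograph. The column
order is normalized so increasing position points away from the soma:
anterograde motion always has positive slope.

`extract_tracks()` replaces manual tracing. Rows are matched-filtered with a
PSF-sized Gaussian, local maxima above a robust threshold (median + k·MAD)
are detected, and detections are linked frame to frame against a
constant-velocity prediction (greedy in ascending prediction error, bounded
by a maximum credible speed). Several measures keep identities intact where
trajectories cross, all validated against simulator ground truth:

* tracks that lose their peak to a merged spot *coast* on their own
  extrapolation and reclaim the peak when it separates;
* predictions of tracks below 0.3 µm/s are held in place (stationary jitter
  carries no usable velocity), and such slow tracks only accept detections
  near their prediction, so a passing vesicle cannot drag them along;
* long-anchored tracks — slow, with 20 frames inside an envelope scaled to
  their own localization scatter — claim their peak with priority: an object
  that has not moved for 15 s does not jump;
* trailing coasted (unconfirmed) points are trimmed when a track closes, and
  severed fragments are rejoined when each extrapolates onto the other's
  endpoint.

Dense three-body encounters can still swap identities occasionally; the
acceptance battery quantifies the residual effect (see below) rather than
assuming it away. Sub-pixel localization refinement and merging/splitting
cargo are out of scope.

## The simulator: what it emulates, and what not

`simulate_transport()` draws a two-state (run/pause) bidirectional transport
process, discretized at the frame interval, for `n_particles` along a
straight axon, plus a stationary sub-population (planted exactly as
`round(stationary_fraction · n_particles)`) undergoing reflected Brownian
motion with `diffusion_coeff` (default 0.01 µm²/s — matching the diffusion
bound's `D`). Runs have exponential lengths (`run_length_mean`, default 8 µm)
and truncated-normal speeds (defaults 1.0 µm/s anterograde, 1.2 µm/s
retrograde, SD 0.2 — literature-typical lysosome values; the defaults are
configuration, not claims about any particular dataset). A run ending by
length exhaustion reverses with `reversal_prob` (0.3) or pauses for an
exponential `pause_duration_mean` (3 s) and resumes; an independent
`pause_rate` hazard (0.02 /s) can interrupt a run mid-flight. Particles
reaching an axon end are absorbed and respawned at the opposite end as a new
particle id, keeping density stationary. Frames are rendered as isotropic
Gaussian spots (`psf_sigma` 1.3 px) over Poisson background; `snr` is peak
amplitude over background noise SD, with `snr = Inf` meaning noise-free
rendering at a fixed bright amplitude.

Three acquisition regimes are bundled: 0.75 s × 120 s, 1 s × 90 s and
2 s × 180 s, at the 630× pixel calibration.

Not emulated: photobleaching, axon curvature, 3-D defocus, merging/splitting
cargo, intensity heterogeneity between particles. A green test therefore
certifies algorithmic correctness under the stated model, not performance on
arbitrary real recordings.

Two subtleties of the stated world deserve note, because they define what
"recovering planted values" can mean:

* the ≥ 5 µm cutoff censors the run-length distribution and sub-threshold
  pauses merge stretches, so no rule-faithful analyzer can recover the
  generative exponential mean; the planted reference for summary statistics
  is instead the rule applied to the true trajectory table
  (`ground_truth_summary()`), which the rendered-pipeline estimates are held
  against;
* the classified stationary fraction in the stated world is ≈ 2.6 points
  above the planted 50% slot fraction: a motile particle absorbed mid-movie
  leaves two fragments that each span less than half the movie and drop out
  of the classification denominator.

Measured on 30-movie batches at defaults, the full
render → kymograph → track → segment pipeline recovers ground-truth speeds,
run lengths and stationary fraction within about 2–4% on noise-free
renderings and within about 9–15% at snr = 5; the stationary fraction is the
weakest of the five at low snr.

## Puncta colocalization and field intensity

`detect_puncta()` thresholds at median + k·MAD (optionally after Gaussian
matched filtering, with intensities still measured on the raw image),
labels 4-connected components, filters by `min_size`, and reports
intensity-weighted centroids and background-subtracted integrated
intensities. `colocalize()` matches two channels one-to-one, greedily in
ascending center distance, accepting pairs up to `coloc_max_distance`
(inclusive); on separable fields this equals the optimal minimum-distance
assignment, which the tests verify by exhaustive enumeration.
`rupture_metrics()` assigns puncta to hand-drawn cell ROIs (even-odd
point-in-polygon; overlap ties go to the first ROI in file order), discards
marker puncta not colocalized with a lysosome punctum as background, and
reports per cell the percent of lysosome puncta carrying the marker plus the
colocalized-marker integrated intensity (RFU). The three detection
parameters must be held identical across all images of an experiment.

`threshold_stats()` applies a threshold of `multiplier` × background
(default 3×) and reports average pixel intensity, integrated intensity and
area over the mask; `per_cell_rfu()` normalizes by a manually counted cell
number. Background defaults to the median of a user-specified cell-free
region, falling back to the image mode. Whether "average intensity" should
be computed above threshold or over the whole field is genuinely ambiguous
in common practice; above-threshold is the default, `whole_field = TRUE`
gives the alternative. Proprietary best-focus Z-projections are replaced by
`focus_project()`: globally sharpest plane by Laplacian variance, or a
per-pixel variant for mixed-focus fields (a documented divergence from any
specific vendor algorithm).

## Group statistics

`two_group_test()` is the unpaired two-sided t test at a 95% confidence
interval — pooled variance on request, Welch–Satterthwaite by default, since
the variance-equality assumption is rarely verified (an F-test pre-check is
available behind `auto_variance`). Two groups with zero variance and equal
means return p = 1 by convention, flagged. `multi_group_test()` is one-way
ANOVA with Tukey HSD post hoc tests, for designs like control/treated ×
±stressor. No multiplicity correction is applied across the many transport
parameters — each parameter is tested on its own, a deliberate mirror of
common practice and a caveat for interpretation. Under a simulated null both
tests hold their 5% level within Monte-Carlo error (asserted at 10,000
replicates), and per-parameter p-values from identically configured
simulated groups are uniform.

Summaries aggregate per movie (axon) first — the movie is the experimental
unit — and are reported as mean ± SEM across movies; per-run pooling is not
the default because runs within one axon are not independent.

## Numerical and interface choices

* All distances in µm, times in s (flux per minute); kymograph positions are
  half-open `[0, L)` with columns centered at half-pixel arc positions.
* Boundary behavior is exact where a rule states a threshold: displacement
  4.99 µm is not a run, 5.00 µm is; excursion 4.99 µm is stationary, 5.00 µm
  motile; punctum area `min_size − 1` is rejected, `min_size` kept; pair
  distance exactly `coloc_max_distance` is accepted.
* "Flux in µm per µm per minute" is the dimensional reading forced by
  `sum(d) / (l · t)`; reported as such.
* The diffusion-bound horizon default stays at the conventional 50 s even
  though movies run 90–180 s; the bound is a justification for the 5 µm
  cutoff, not a fitted quantity, and both are configurable.
* TIFF I/O is a deliberately minimal reader/writer for uncompressed
  little-endian grayscale stacks (8/16-bit integer, 32-bit float), round-trip
  tested and cross-checked against an independent implementation; compressed
  or RGB files are rejected loudly rather than mis-read.
* Configs and run manifests are JSON; manifests carry md5 checksums of every
  output so deterministic stages can be verified byte-for-byte.

## Known limitations

* Tracking is a local linker with healing, not a global assignment over the
  whole movie; dense crossings can swap identities, quantified by the
  parameter-recovery battery rather than eliminated.
* The stationary/motile classification needs a track spanning at least half
  the movie; heavily fragmented recordings bias the classified population.
* ROI assignment uses punctum centroids only; a punctum straddling an ROI
  border belongs wholly to the ROI containing its centroid.
* The simulator's spot amplitudes are uniform across particles; detection
  thresholds calibrated on it may need adjustment for real data with wide
  intensity ranges.
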