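---
title: "Methods: clustering quiet-standing postural sway from marker trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering quiet-standing postural sway from marker trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swayclust)
```

## The problem

During quiet standing the body oscillates continuously — postural sway. In
post-stroke patients the spatial pattern of that sway carries clinical
information, but summary measures of the center of pressure alone have
correlated poorly with demographic factors such as days after stroke onset.
`swayclust` implements an alternative: treat each short window of a
multivariate motion-capture recording as an object, cluster those objects by
their temporal shape, and only then ask which kinematic variables
distinguish the clusters and how cluster membership relates to recovery
time.

The data model is a cohort of quiet-standing trials. Each trial records 10
reflective markers (shoulder, hip, knee, ankle, toe; both sides) plus the
whole-body center of mass (COM), each with X/Y/Z displacement — 33 kinematic
variables — sampled at 60 Hz for 30 s. X is the medial-lateral (ML)
direction, Y anterior-posterior, Z vertical. Each trial carries subject
metadata: disease type (cerebral hemorrhage, CH, or cerebral infarction,
CI), age, days after onset, and hemiplegia side.

## Preprocessing

`preprocess_cohort()` applies four steps, in order, per recording:

1. **Offset** (`offset_by_ankle_midpoint()`): the time-averaged midpoint of
   the two ankle markers is subtracted from every variable, per axis. We
   subtract one constant vector per recording rather than the per-sample
   midpoint: per-sample subtraction would remove the ankle markers' own sway,
   which the downstream analysis treats as a first-class variable.
2. **Anthropometric scaling** (`scale_by_height()`): every value is divided
   by `l1 + l2 + l3`, the summed mean shoulder–hip, hip–knee and knee–ankle
   marker distances (`compute_segment_lengths()`; means over time and both
   sides). This makes the data dimensionless and maps geometrically similar
   bodies onto identical trajectories, which is the property the whole
   pipeline leans on — it is applied exactly once.
3. **Filtering** (`lowpass_filter()`): a double-pass (forward–backward)
   second-order Butterworth low-pass at 12 Hz, applied per column. The double
   pass gives zero phase lag and squares the magnitude response. Coefficients
   come from `signal::butter()`; the zero-phase wrapper pads both ends by odd
   (point-reflected) extension — at least 60 samples — so each pass's start-up
   transient falls in the discarded pad. Filtering happens before slicing so
   slot edges carry no transient.
4. **Slotting** (`slice_slots()`): the recording is cut into consecutive,
   non-overlapping, left-aligned windows of `t` seconds ("data slots"); a
   trailing remainder shorter than one window is discarded. A 30-s recording
   gives 6 slots at `t = 5` (300 samples each), 5 at `t = 6`, 3 at `t = 10`.

## DTW distance and cluster models

Slots are compared by dynamic time warping (DTW), which tolerates the speed
variation inherent in sway: `dtw_distance()` uses the symmetric step pattern
with unit weights, no warping window, and no path-length normalization (all
compared slots have equal length, so normalization would only rescale every
distance by the same constant — these choices are stated as package defaults,
not field-wide conventions). Two multivariate modes exist:

* **independent** (default): univariate DTW per kinematic variable, the 33
  distances summed — each variable of one slot is compared with the
  corresponding variable of another;
* **dependent**: a single alignment over time with local cost the Euclidean
  norm across all 33 variables.

The phrase "compare each vector of one slot with the corresponding vector of
another" is genuinely ambiguous between these two readings, so both are
implemented and every clustering entry point takes a `mode` argument; the
defaults use the independent reading. The two modes coincide for univariate
sequences, which the test suite exploits.

The dynamic program is written in C++ (via Rcpp) with O(min(n,m)) rolling
memory: a 186-slot cohort needs 17 205 pairwise alignments of 300-sample,
33-variable slots, which is far outside pure-R loop budgets. Ties in the DP
step choice prefer the diagonal; this affects only the reported warp path,
never the distance.

Two cluster models operate on this geometry:

* **DTW-PAM** (`pam_cluster()`): k-medoids over the precomputed distance
  matrix. Medoids are initialized uniformly at random (matching the
  randomly-initialized-centroid design the pipeline reproduces, rather than
  the deterministic Kaufman–Rousseeuw BUILD phase), then improved by
  steepest-descent swaps until no single medoid/non-medoid exchange lowers
  the total cost. The whole run is repeated 10 times (configurable) and the
  lowest-total-cost solution kept; selection is by cost, not by a validity
  index, so the index evaluation stays out-of-loop.
* **DTW-DBA** (`dba_cluster()`): k-means-style iteration whose centroids are
  DTW barycenter averages (`dba_average()`). DBA initializes at the medoid
  member (deterministic), aligns members to the current average and replaces
  each average sample by the mean of the samples warped onto it; the summed
  cost is non-increasing and iteration stops on a small decrease. An emptied
  cluster is re-seeded with the slot farthest from its centroid.

## Validity indices and the model-selection grid

Slot length `t` and cluster count `K` are selected on a grid
(`grid_search()`, default `t ∈ {3, 5, 6, 10}` s, `K ∈ {3, 4, 5}`) scored by
three indices: Davies-Bouldin (lower better), Calinski-Harabasz (higher
better) and Dunn (higher better). Because the clustered objects are
sequences, all three are evaluated **in DTW-distance space**: member-to-
centroid gaps are DTW distances to the medoid (PAM) or DBA average (DBA),
and squared DTW distances replace the squared Euclidean deviations in the
Calinski-Harabasz sums of squares, with the global center taken as the
overall medoid (PAM) or whole-set DBA average (DBA). This is the main point
where the underlying procedure is under-specified; computing indices in the
same geometry the clustering optimizes is the consistent choice, and it is
what the package documents and tests. For the Dunn index the standard
definition (minimum between-cluster distance over maximum cluster diameter)
is used. The indices are reported for every grid cell; a single cell is
flagged by a majority vote of the three indices with the Calinski-Harabasz
value as tie-break — but the full table is always returned, because the
three indices legitimately disagree and a human should see the table.

## Sway features and post-hoc comparisons

`featurize()` reduces each (slot, variable) pair to three parameters:

* **amplitude** — max minus min within the slot;
* **SD** — sample standard deviation (denominator `n − 1`);
* **sway frequency** — the frequency of the maximum-magnitude FFT bin,
  excluding DC and the Nyquist bin, after mean removal. No taper window is
  applied (the signal is already low-passed and offset); the resolution is
  `rate/length` = 0.2 Hz for 5-s slots. "Most prominent peak" is read as the
  global spectral maximum because it is deterministic and parameter-free; a
  constant series yields `NA`.

`build_significance_table()` compares each parameter between clusters, per
variable. The branch is gated per (variable, parameter) family
(`gate_test_choice()`): Tukey-Kramer only if every cluster passes
Shapiro-Wilk *and* Bartlett's test passes (both at `alpha_gate = 0.05`);
any failure — including undefined tests on constant groups — routes to
pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment across
the `choose(K, 2)` pairs of that family. The rank-sum (Mann-Whitney) form is
used because cluster groups are disjoint slot sets, not paired observations.
Correction is within-family only, matching per-row reporting; no correction
is applied across the 33 variables. α and the gate level default to 0.05.
One caveat is inherited deliberately: slots cut from the same recording are
not independent observations, and the procedure treats them as exchangeable
anyway — this reproduces the slot-level design faithfully and should be read
with that in mind.

`build_transition_table()` tabulates per-session slot labels against days
after onset with a majority ("main") cluster per session; ties resolve to
the lowest cluster index and are flagged. `cluster_characteristics()`
summarizes per-cluster demographics (median onset days, median age, disease
mix).

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` builds cohorts
with planted structure so that every stage is testable. The generative model
per recording is: a static standing pose assembled from the subject's
segment lengths, plus per-marker sway equal to a single sinusoid at the
planted cluster's frequency (random phase per recording and axis, small
per-marker phase jitter) scaled by marker baseline amplitude times the
cluster's multiplier, plus low-pass-filtered Gaussian noise; the COM is a
fixed trunk-heavy weighted mean of the markers.

Defaults mirror the study conditions the pipeline targets: 31 recordings of
30 s at 60 Hz; 4 planted clusters; cluster frequencies 0.6/0.8/1.2/1.4 Hz —
inside the 0.5–1.5 Hz band reported for post-stroke sway and aligned to the
0.2 Hz bin grid of 5-s slots so spectral recovery is exact; amplitude
multipliers 1/2/3.5/5; upper-body baselines (shoulder 20 mm, hip 15 mm)
larger than lower-body (knee 8, ankle 4, toe 2 mm); noise SD 1.5 mm
low-passed at 10 Hz; a CH/CI mix of one half each. Subjects are
geometrically similar up to a global body-size factor (0.9–1.1) with ±2%
independent segment-proportion jitter; this matters, because the
anthropometric scaling step can only remove size variation that is close to
geometric similarity — which is also true of real bodies and is the reason
the scaling step exists. `planted_onset_drift()` adds repeated sessions in
which CH subjects step through clusters 4→3→2→1 as onset days grow while CI
subjects keep one cluster, emulating the recovery-transition pattern the
transition table is designed to expose.

What the generator does **not** emulate: inverted-pendulum dynamics,
broadband (pink) sway spectra, marker dropout or soft-tissue artifact, and
any quantitative left/right asymmetry (a symmetric default ratio of 1 is
provided as a knob). Passing tests on this generator therefore validate the
pipeline's machinery — preprocessing algebra, DTW/PAM/DBA optimization,
index arithmetic, test gating — not the clinical claim that real post-stroke
sway forms four clusters.

## Numerical choices and degenerate inputs

* Distances and DP accumulation in double precision; DP ties prefer the
  diagonal step.
* PAM swap acceptance requires an improvement > 1e-12 to avoid cycling on
  ties; medoid ties resolve to the lowest slot index.
* Davies-Bouldin raises an error on coincident centroids (zero gap);
  Calinski-Harabasz returns `+Inf` with a warning when the within-cluster
  sum of squares is zero, as does Dunn for a zero diameter.
* Constant series: amplitude and SD are 0, sway frequency is `NA`;
  Shapiro-Wilk on a constant group is undefined and routes the family to
  the Wilcoxon branch; identical zero-variance groups compare at `p = 1`.
* The CSV loader rejects missing values by default; an opt-in linear
  interpolation bridges interior gaps of at most 5 samples.

## Problem sizes used in validation

The shipped validation uses cohorts at the full study shape (31 × 30 s)
where the claim is structural (slot counts, shapes), and reduced cohorts —
31 recordings shortened to 15 s for cluster recovery across 10 seeds, 8
subjects × 4 sessions × 15 s for the onset-drift table — where the claim is
statistical
and the full 186-slot distance matrix would be recomputed many times over.
These sizes are the package's own validation design; the acceptance script
(`scripts/acceptance.R`) runs the full 31 × 30 s cohort end-to-end once.

## Known limitations

* DTW distances do not satisfy the triangle inequality; the validity
  indices inherit that geometry, and their absolute values are not
  comparable with Euclidean-space implementations.
* Selection among the three validity indices is a heuristic vote; on real
  data the full grid table should be inspected.
* The slot-level post-hoc tests ignore within-subject correlation (see
  above); a mixed-model treatment is deliberately out of scope.
* The TRC motion-capture format is not parsed; recordings enter as CSV (a
  TRC reader would sit behind `read_recording()`'s contract).
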