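---
title: "Reconstructing the myofibrillar matrix: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the myofibrillar matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myomatrix)
```

## The measurement problem

In striated muscle imaged by volume electron microscopy, each myofibrillar
segment between junctions can be traced and given a unique integer label.
Where a sarcomere segment splits into two the tracing protocol ends the
parent label and starts two fresh labels; merges mirror this. The result is
a labeled 3D volume in which the *topology* of the contractile apparatus —
how often sarcomeres branch, how severely (two vs three-plus resultant
segments), where in the cell — is implicit in how label footprints succeed
one another along the muscle's long axis. `myomatrix` makes that topology
explicit and summarizes it the way the field reports it: per muscle cell,
with myofibrils tracked from a seed cross-section and sarcomeres counted
between sarcotubular (SRT) planes.

Conventions used throughout: arrays are indexed `(long, row, col)` with the
longitudinal axis first (use `reorient_longitudinal()` on other layouts;
only axis permutations and flips are supported — arbitrary-angle resampling
would corrupt labels and is deliberately out of scope). Voxel sizes are in
nanometres. All randomness is controlled by explicit seeds.

## Segment graph model

Two labels are connected when the second's first occupied cross-section
begins within `max_gap` slices after the first's last occupied
cross-section *and* their footprints intersect in at least `min_overlap`
voxels (default 1: tracings are interpolated and already smooth; raise it
for noisy instance segmentations). `max_gap` exists because SRT planes
interrupt labels at sarcomere boundaries; its default, 4 slices, covers a
40 nm SRT gap at 20 nm voxels plus rounding, and should be set to
`ceil(gap / voxel) + 2` for other geometries. Gaps *within* one label are
bridged by identity; a label reappearing after more than `max_gap` empty
slices is almost certainly label reuse and raises an error rather than a
silent mis-link.

A label with `k >= 2` successors is a split; with `k >= 2` predecessors a
merge; one-to-one links are continuations and generate no event. Events
with `max(parents, children) == 2` are *single*, `>= 3` *multi*, and carry
`branch_count = max(parents, children) - 1`. Splits and merges both count
as branching — reversing the longitudinal axis maps one onto the other, and
the branching statistics are invariant under that reversal (a property the
test suite checks).

### Sarcomere counting

A segment's sarcomere count is read from SRT crossings along its centroid
track: the count of inter-SRT intervals it spans. Terminal partial
intervals (at the volume ends, or where a segment begins/ends mid-course)
are counted only when at least half the local sarcomere length — the median
complete interval, or a supplied nominal length. This rule makes the
realized branching fraction an unbiased estimator (see the generator
section) and handles the fibrillar-muscle case, where SRT content is ~1% of
the cell and crossing detection is unreliable, through the
`nominal_sarcomere_length` fallback (`round(length / nominal)`, minimum 1).

### Tracking and censoring

One track is seeded per label in the first occupied cross-section. At each
split the tracker follows the successor whose mean sarcolemma distance is
closest to the *seed* segment's — the structure that best keeps its radial
place in the cell. Distances are sampled at per-slice centroids, so they
are meaningful only at voxel resolution: successors within one in-plane
voxel of the minimum are treated as tied and resolved to the smaller label
(labels are created in tracing order, so this prefers the earlier-traced
continuation deterministically). A track is censored when any of its
segments touches a lateral volume face or when it ends more than `max_gap`
slices before the last occupied cross-section; censored tracks are excluded
from all per-track statistics.

Each event is attributed to the sarcomere immediately upstream of its
junction plane (an event upstream of the first counted sarcomere attributes
to that sarcomere, which keeps the attribution symmetric under axis
reversal). A sarcomere with events at both boundaries counts once toward
the branching percentage but contributes every `branch_count` to the
branch-frequency numerator.

## The synthetic generator as a stated world

`generate_muscle_volume()` emulates exactly the features the analysis
consumes: parallel quasi-cylindrical myofibrils on a square lattice;
periodic sarcomeres separated by thin SRT planes; junction events at
sarcomere boundaries; an enclosing cell mask. Per (myofibril, sarcomere),
at most one event occurs: single with probability `p_single`, multi with
`p_multi` (multiplicity `k` from `multi_multiplicity_pmf`), realized as a
merge with probability `p_merge_fraction` (default 0.5) and a split
otherwise. Every resultant segment receives a fresh label.

Defaults state a realistic tubular-muscle world at analysis resolution:
20 nm voxels (10 nm acquisition binned by 2), 3.2 µm sarcomeres, 0.4 µm
myofibril radius, 40 nm SRT gaps. Tests and the acceptance suite use the
same layout with radius 80 nm / sarcomere 800 nm so that the prescribed
desk-scale grids (64 × 64 cross-sections, ~500 slices) host 3 × 3 bundles
of 10-sarcomere myofibrils; this scaling changes no algorithmic behavior,
only run time.

Two design points matter for estimator correctness:

* **Events are atomic.** A split is realized as the parent ending and a
  continuing child plus short *stub* children beginning; stubs end
  mid-sarcomere rather than re-merging, because a compensating merge would
  double the realized event rate and break the closed-form expectations in
  `expected_statistics()` (`pct = 100 (p_single + p_multi)`,
  `branches_per_10 = 10 (p_single + p_multi E[k-1])`). Merges mirror this
  construction backwards. Stub offsets are placed equally spaced around the
  parent axis within 1.5 radii, so lanes never collide and sibling stubs
  never touch.
* **Half-sarcomere pads.** Volumes begin and end with ~0.3-sarcomere pads
  beyond the outermost SRT plane. Every counted sarcomere therefore has
  both boundaries inside the field of view and is eligible for an event, so
  the realized branching fraction is an unbiased binomial estimate of
  `p_single + p_multi`; without the pads the last sarcomere could never
  branch and every estimate would be biased low by a factor `(n-1)/n`. The
  pads themselves are below the half-length threshold and are not counted.

The default multiplicity pmf (over `k` = 3..6) is calibrated so that
`E[k-1] = (1.30 - 0.272)/0.387 = 2.656`, the value obtained by inverting
the highly branched leg-muscle regime's branches-per-10 from its
single/multi rates; the published record does not constrain the
multiplicity distribution further, so the pmf is a free configuration
parameter. `muscle_type_rates()` derives `(p_single, p_multi)` pairs for
each published regime the same way, falling back to the leg single:multi
ratio where only a total percentage was reported (DF and NCDN-KD regimes).

With `peripheral_bias > 0` the per-myofibril event rate is reweighted by
`exp(bias * (1 - d/d_max))` toward the cell boundary while the *mean* rate
is held at `p_single + p_multi`; with bias 0 event positions are uniform
over (myofibril, sarcomere), which is the null the spatial test is
calibrated against. `n_exiting` adds myofibrils that drift out of the
lateral face (one lateral jump per SRT plane, small enough to preserve
footprint overlap) to exercise censoring; they carry no events.

What the generator does **not** emulate: EM texture or noise, anisotropic
or curved myofibrils, mitochondrial geometry, z-disk holes and streaming
morphologies, partial-volume label errors, and overlapping/touching
myofibrils. A green recovery test therefore establishes that the graph
machinery is exact on clean separable geometry — not that segmentation
errors are tolerated; `min_overlap` and `max_gap` are the knobs to study
for robustness on real tracings.

## Morphometry

CSA is voxel count times in-plane voxel area. The perimeter estimator is
the perimeter of the convex hull of the label's pixel centers plus `pi`
times the pixel pitch (a Minkowski dilation by half a pixel). For convex
digitized shapes this converges to the true Euclidean boundary length —
a radius-50 digitized disk measures circularity 0.984, a 20-pixel square
0.80 (`pi/4` is exact for a true square), a 40 × 20 rectangle 0.71 —
whereas raw crack-edge counting overestimates a circle's perimeter by up to
27% and chain codes with sqrt(2) diagonals still by ~5–6%, which would make
even a perfect disk measure ~0.90. The price is that deep concave
indentations are bridged: circularity of highly non-convex profiles is a
convex-compactness measure. Myofibril cross-sections are compact blobs, the
regime this estimator is designed for; circularity is capped at 1.
Multi-component label slices are bridged by one hull and flagged as a known
limitation. Degenerate inputs are defined: a single pixel has perimeter
`pi * h` (a half-pixel disk), collinear pixels twice their extent plus the
dilation cap.

Per-myofibril CSA is the mean over the myofibril's occupied slice
measurements (the aggregation rule is not uniquely dictated by practice;
the mean over slices weights long segments proportionally). The
volume-weighted mean CSA `sum(c^2)/sum(c)` is always at least the
arithmetic mean (Cauchy–Schwarz, equality iff all equal) — the property
that makes it sensitive to a few large myofibrils dominating the volume.

The boundary distance map is an exact anisotropic 3D Euclidean distance
transform (separable lower-envelope algorithm in C++). Volume faces are not
treated as boundary: only genuine background voxels attract distance, so a
cell mask spanning the full stack measures lateral sarcolemma distance
only.

`peripheral_bias_test()` uses `median(reference) - median(branch)` with a
label-shuffling permutation null, one-sided toward "branches closer to the
boundary". Medians resist the skew of distance distributions in irregular
cells; the permutation count floor (1000) bounds the attainable p-value at
~1e-3 and the test is calibrated (at most ~5% false rejections under the
generator's uniform null, verified over 100 seeds in the acceptance suite).

## Group statistics

`superplot_table()` treats cells as the unit of replication: the overall
mean and SE are computed over cell means, never pooled myofibrils, and a
single cell reports SE as unavailable rather than 0. `compare_groups()`
implements the published decision tree: for >2 groups, one-way ANOVA with a
Brown–Forsythe gate (ANOVA on absolute deviations from group medians)
choosing Tukey HSD (variances compatible) or Dunn's all-pairs rank
comparisons (variances different; classic z statistics with tie correction
and Bonferroni family-wise adjustment — the correction flavor is not
pinned down by practice, so the most conservative classic choice is used).
For two groups, Shapiro–Wilk on each group gates a two-sided pooled t-test
against the rank-based fallback. The protocol this mirrors names the
*signed-rank* test for that fallback, which is a paired test; with
independent group designs the coherent rank-based analogue is the rank-sum
test, and the result object records this divergence in its `notes` rather
than silently substituting. Groups with fewer than two replicates produce
descriptive output only. Every gate decision and p-value is retained in the
result object, and rank ties are handled by deterministic average ranks, so
reruns are bit-identical.

Type-I calibration (null ANOVA rejection 5% ± 1.5% over 1000 replicates)
and gate sensitivity (Brown–Forsythe routes 100-fold variance inflation to
Dunn in ≥95/100 replicates) are asserted in the acceptance suite.

## Numerical choices and degenerate inputs, collected

* Probability threshold is `>=` (exactly 0.5 is foreground); binarization
  dialects differ and this one is stated.
* Outlier removal: per-slice disk-median filter, replacement when the
  deviation exceeds `k_sd` × the slice SD (defaults 3 px / 2.0 SD, inside
  the conventional 3–10 px / 1.5–2 SD working range); uniform slices have
  SD 0 and are untouched, making the operation idempotent there.
* Structure masks must be disjoint for volume fractions; overlapping
  probability exports are resolved by max-probability assignment with a
  stated priority order (contractile > mitochondria > SRT) for exact ties.
* Label binning uses the per-block modal positive label, ties to the
  smallest label; background wins only in all-background blocks.
* 8-bit probability files map linearly 0–255 to 0–1; writing quantizes to
  the nearest 1/255.
* Tracking tie tolerance: one in-plane voxel of boundary distance.
* Fold-change targets and regime rates are recomputed from published group
  means at run time, never stored as results.

## Known limitations

Arbitrary-angle reorientation, instance segmentation itself, z-disk hole
detection, surface meshing, and rendering are out of scope. The perimeter
estimator bridges concavities (above). Tracking assumes junction-consistent
labels (fresh labels after every event); volumes that reuse labels across
junctions are rejected rather than repaired. The generator's myofibrils
are axis-aligned and non-touching; recovery guarantees do not extend to
overlapping instances. Sarcomere counting in SRT-poor (fibrillar) muscle
relies on the nominal-length fallback, whose rounding is a stated
approximation.
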