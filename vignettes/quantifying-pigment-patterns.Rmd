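---
title: "Quantifying pigment-cell patterns with persistent homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pigment-cell patterns with persistent homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigmentr)
```

## The problem and the model of the data

Pigment-cell patterns — stripes, interstripes, and the spotted phenotypes of
mutants missing a cell type — are recorded as tables of cell coordinates:
one row per cell, a cell-type label, and (x, y) positions in micrometres on
a rectangular patch of skin. `pigmentr` treats that patch as a cylinder:
periodic in x (a stripe runs around the fish flank, and on the analysed
patch a complete band re-enters where it left) and walled in y. Under this
metric a complete band is a topological loop and a spot is a plain connected
component, which turns "how many stripes?" into a Betti-number computation.

Two preprocessing steps are assumed throughout: x coordinates are
canonicalized into `[0, length_x)` on load, and the top and bottom 10% of
the domain are trimmed (`trim_margins()`) before any snapshot analysis,
because partially formed bands and spots accumulate against the horizontal
walls. Formation-time detection is the one exception: it runs on untrimmed
patterns, since trimming would mask exactly the boundary growth it looks
for.

## Persistence conventions

`compute_persistence()` computes Vietoris–Rips persistent homology in
dimensions 0 and 1 from the pairwise cylinder distances. Two conventions
matter:

* **Ball-radius scale.** Births and deaths are reported at half the
  pairwise distance: growing balls of radius r around cells, two cells
  connect when r reaches half their separation. On this scale the
  cell-spacing thresholds below apply literally, and twice a band loop's
  persistence estimates the width of the band it encloses. A
  `scale = "distance"` toggle reports unhalved filtration values for
  comparison with tools that threshold on distances.

* **Filtration cap.** The filtration is truncated at
  `max_radius = min(length_y / 2, length_x / 8)` (overridable). Features
  alive at the cap are reported with `death = Inf`. The upper bound in x is
  deliberate: on a cylinder the one cycle that wraps the domain through a
  complete band dies only when the Rips complex fills the periodic
  direction, at roughly `length_x / 6` on the radius scale. Keeping the cap
  below that scale pins the wrap cycle at infinity, which gives the two
  statistics built on the diagram clean semantics (next section). Band-merge
  deaths — the ones that carry width information — occur near half the
  band-to-band gap, far below the cap for any pattern whose bands fit the
  domain. Widths larger than the cap would be reported as essential and
  excluded; for such data raise `max_radius` explicitly.

Rips rather than the ball-union (Čech) construction is used because every
decision downstream is threshold-based with wide margins relative to the
Rips/Čech discrepancy. The one place the discrepancy is visible is exact
width arithmetic: two parallel cell rows with in-row spacing s and gap g
merge as components at g/2, but their loop dies at the diagonal,
`sqrt(g^2 + s^2) / 2`. The width estimate `2 * (death - birth)` therefore
recovers `sqrt(g^2 + s^2) - s` rather than `g - s`; for bands at realistic
spacings the difference is a fraction of one cell spacing and is covered by
the tests' one-cell-spacing tolerance.

Internally, dimension 0 is a union-find pass over the sorted edge list, and
dimension 1 reduces the coboundary matrix (persistent cohomology, which
yields the same pairing as homology) with merge edges cleared, lazy-heap
working columns, and on-demand rebuilding of unchained columns; output
ordering is deterministic (features sorted by dimension, birth, death).
The suite cross-checks the engine against an independent dense GF(2)
boundary-matrix reduction written in plain R on random small instances, and
against union-find and minimum-spanning-tree oracles on larger ones.

## Thresholds and counting semantics

`quant_config()` carries the thresholds, all in micrometres on the radius
scale:

| parameter | default | meaning |
|---|---|---|
| `tp0` | 100 (Id, Il), 90 (M) | minimum dim-0 persistence: a spot must survive this long before merging |
| `tp1` | 200 (all types) | minimum dim-1 persistence for a band loop |
| `tb1` | 100 (Xl), 80 (Xd), 90 (M) | maximum birth radius of a countable loop |
| `trim_fraction` | 0.1 | margin trim |
| `formation_threshold` | 200 | bound jump that dates a new stripe |
| `d0`, `d1` | 32, 62 | formation search window (dpf) |

The dim-0 rule is strict (`persistence > tp0`) and always counts the
essential component; `tp0` sits well above half the 30–80 µm neighbour
spacing, so cells within one spot never count separately. The dim-1 rule is
inclusive on persistence (`>= tp1`) and bounded in birth (`<= tb1`): a
complete band becomes a loop at half its largest internal cell gap (well
under `tb1`), while a band broken by a gap G only closes at G/2, so breaks
disqualify the loop. These comparison directions are fixed and tested.

One design choice deserves emphasis: **counting treats capped features as
infinitely persistent, width uses finite features only.** Each unbroken
band contributes one loop, but after all bands of a type merge, exactly one
representative cycle per connected component survives to the cap. Excluding
it would systematically undercount complete bands by one (three unbroken
interstripes would report β₁ = 2); including capped features in width would
instead report the x-fill scale of the domain rather than a band width. The
split rule makes both statistics measure what they claim: with the default
cap, any capped loop born under `tb1` is a genuine band (its persistence
provably exceeds `tp1` because the cap exceeds `tb1 + tp1`).

## Clustering-based statistics

Single-linkage clustering (`cluster_pattern()`, delegated to
`stats::hclust`/`cutree` on the cylinder distance matrix) partitions cells
into a requested number of clusters; it is the dendrogram counterpart of
dim-0 persistence and, unlike centroid methods, keeps elongated and
undulating bands intact. Tests verify the partition equals cutting the k−1
longest edges of the minimum spanning tree. Per-cluster summaries unwrap
clusters straddling the x seam (members are shifted by one period, cutting
the circle at its largest empty arc) before computing the centroid, the PCA
eigenvalues of the member covariance, and the diameter (twice the largest
centroid-to-member distance).

* **Spot size** is the median cluster cardinality, with the *lower* median
  on even counts (sizes are integers; interpolating would fabricate
  half-cells).
* **Roundness** is the median λ₁/λ₂ over clusters with at least 3
  non-collinear members (degenerate clusters are excluded with a warning),
  midpoint-interpolated on even counts since the ratio is continuous.
  λ₁/λ₂ estimates the squared axis ratio of an elliptical spot.
* **Spot spacing** is the sample SD (n − 1) of each centroid's
  l<sub>∞</sub> distance to its nearest neighbour, with the x component
  wrapped and the y component plain, matching the domain's boundary
  conditions.
* **Centre width** is `2 * min(centroid distance to domain centre) -
  median diameter`, floored at zero (a spot overlapping the centre would
  otherwise yield a meaningless negative clearance). The literal reading —
  distance to the centre *point* — is the default; `midline = TRUE`
  switches to vertical distance from the horizontal midline, which differs
  when no spot column passes near the centre x.

**Curviness** measures stripe straightness from band clusters of interstripe
cells: each cluster's upper and lower boundary polylines are extracted by
binning x and taking the per-bin extreme y; their summed arc length (ALD) is
compared with the straight-band value `2 * length_x`, and the statistic is
the mean percentage excess. The bin width defaults to twice the pattern's
median nearest-neighbour spacing — the smallest bin that always contains a
full lattice column, so the envelope follows the band edge instead of
sawtoothing between lattice rows. Positional jitter still leaves a small
noise floor (about 1% at 15% jitter; measured by the test suite on straight
bands), which is why curviness comparisons should be made at matched
density and jitter. Clusters that do not span the full period are excluded
from the mean with a warning; the number of clusters requested follows the
loop count, so a detected break reduces it.

**Formation times** scan a day-indexed series of interstripe-cell snapshots
within `(d0, d1]` and report the first day the pattern's maximum y grows, or
minimum y drops, by more than `formation_threshold` relative to the previous
day. Only coordinate bounds are computed — no per-day persistence — so the
statistic is cheap and robust to bound jitter below half the threshold
(tested). The window defaults assume prior knowledge of when new stripes can
form; set `d0`/`d1` to the first and last observed day when there is none.

## The synthetic generator

The generator is first-class, tested code: it is how every statistic is
validated, and its defaults define the study conditions for this package.

Cells are laid out by hexagonal packing at a target spacing (default 50 µm,
within the measured 30–80 µm range) with Gaussian positional jitter of 15%
of the spacing — the near-regular spacing that the persistence thresholds
assume. The default banded pattern puts three interstripe bands (350 µm
wide) and two stripe bands (350 µm) on a 3000 × 2200 µm domain with 75 µm
cell-free boundary margins, so adjacent same-type bands sit 500 µm apart
edge-to-edge; these proportions were chosen once so that five bands fit the
measured domain height with loop persistences comfortably above `tp1`.
Undulation follows a planted sinusoid, breaks punch cell-free arcs into
chosen interstripes, spot patterns place hexagonally filled ellipses on a
row lattice (with optional centre jitter, planted central clearance, and
scattered lone cells), and snapshot series plant dorsal/ventral band
appearance days. Every generator returns its ground truth alongside the
points, and fixed seeds give byte-identical output without disturbing the
caller's RNG stream.

What the generator does **not** emulate: cell–cell interaction dynamics (it
is phenomenological, not mechanistic), domain growth, density gradients,
mixed cell types within a band, irregular spot shapes beyond ellipses, and
segmentation noise such as missed or doubled cells. Passing tests therefore
demonstrate that the statistics recover planted structure under realistic
spacing and jitter — not that they are robust to every artefact of real
imaging data. The break-detection and formation rules in particular assume
the expected band counts and formation windows of the wild-type-like stage
being analysed.

## Numerical choices and degenerate inputs

* Deterministic everything: sorted simplex orders with fixed tie-breaks,
  seeded generators, and a pipeline that is byte-identical on identical
  input and configuration (tested).
* Duplicate points are legal; they create zero-persistence features that no
  thresholded count sees.
* Empty patterns: an explicit error everywhere except `count_spots()`,
  which returns 0 with a warning (an empty mutant pattern is a legitimate
  "no spots" observation).
* `max_band_width()` raises a typed `pigmentr_no_bands` error rather than
  returning a silent zero when no significant finite loop exists.
* Boundary-exact points are kept by `trim_margins()` (closed interval); the
  choice only affects measure-zero configurations.
* Problem sizes: the validation suite runs on patterns of roughly 150–1700
  cells (a full three-interstripe pattern is ~1100 interstripe cells), a
  200-point figure-eight benchmark shape, 50 random oracle instances of up
  to 200 points, and spot counts up to k = 20 across seeds; these sizes
  exercise every code path while keeping the whole suite around a minute.

## Known limitations

* Counting assumes the pattern class is known (bands of the expected count,
  or spots); labyrinthine patterns and automatic classification are out of
  scope.
* Width is an upper-bound-style estimate of the *maximum* band separation;
  it says nothing about mean width, and the dim-0 lower-bound variant is
  not implemented.
* The default filtration cap must sit between the largest band-merge scale
  and the domain's x-fill scale; extremely wide bands on short domains can
  violate this, in which case `max_radius` must be chosen manually.
* Statistics are reported per snapshot; nothing tracks feature identity
  across days except the bound-jump formation heuristic.
* Input is cell coordinates; extracting coordinates from images is an
  upstream problem this package does not address.
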