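---
title: "Mapping flow-cytometry images to plate positions with marker-bead sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping flow-cytometry images to plate positions with marker-bead sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mapping problem

An imaging flow cytometer records a rich image of every cell as it passes in
flow; a robotic dispenser then deposits the same cells, in first-in-first-out
(FIFO) order, onto a porous membrane where they can be picked up individually
for downstream assays. If the FIFO order were perfect, the i-th recorded
image would belong to the i-th object on the plate and mapping would be
trivial. It is not perfect: objects occasionally get trapped in the fluidics
and never reach the plate (*deletions*), and disturbances of the laminar flow
can scramble the local order (*misplacements*). Over a run of 10^5 objects
even rare errors destroy a naive index-based mapping, because a single
deletion shifts every later assignment by one.

`beadmap` implements the marker-bead solution to this problem. Nonfluorescent
polystyrene beads of three sizes — 10, 20 and 30 µm, encoded as the symbols
`A`, `T` and `C` — are premixed with the cells at a cell:marker ratio of 2:1.
Both instruments therefore observe the same sequence over a three-letter
alphabet, interrupted by cells. In sequence terms the beads act like introns
anchoring the cell "exons" between them: aligning the two marker-symbol
strings localizes every disagreement, and the cells between two verified
markers can then be checked independently by comparing counts.

## Event streams and the error model

`generate_stream()` draws the ground-truth FIFO stream: `n_markers` beads
with i.i.d. symbols and `round(ratio * n_markers)` cells, interleaved
uniformly at random (all arrangements equally likely — the generator models
positions, not arrival times). At the design ratio of 2 the mean interior
gap holds 2 cells, which keeps per-gap count verification informative.

Two error processes corrupt a stream:

* `apply_deletion(stream, rate)` removes each event independently with the
  given probability, preserving the order of survivors.
* `apply_misplacement(stream, rate, max_shift)` selects each event
  independently and relocates it by a uniformly drawn nonzero offset within
  `max_shift` positions (default 5). The displacement distribution of real
  scrambling events is not observable from the published experiments; the
  local-uniform model reflects the physical intuition that flow disturbances
  reorder neighbours, and `max_shift = Inf` (uniform random destination) is
  available to model objects that are held up and re-enter much later. Every
  quoted misplacement-detection figure is conditional on this choice and the
  package reports the model parameters alongside every curve.

Both processes apply to cells and markers alike in pipeline simulations; the
sequence-level Monte Carlo study below corrupts marker-only streams. A third
imperfection, out-of-focus imaging ("O" objects), is modelled as a cell
attribute at generation time: such cells still occupy their position in the
order (so they matter for counting) but are flagged unusable for analysis.

## Alignment

`global_align()` computes a maximum-score global (Needleman–Wunsch)
alignment with linear gap penalties in C. Default scores are match +5,
mismatch −4, gap −8 — the NUC44-style values of the standard nucleotide
global aligners this step is modelled on. Linear rather than affine gaps:
bead losses are independent events, not bursts. The traceback tie-break is
fixed (diagonal, then gap-in-plate-track, then gap-in-image-track), so
results are deterministic. All coordinates are 1-based, matching how the
consensus maps are read.

For long sequences the dynamic program runs in a diagonal band centred on
the line from (0,0) to (n,m). The initial half-width is
`max(64, |n − m| + 4 * sqrt(min(n, m)))`; whenever the optimal path touches
the band boundary the band is doubled and the alignment recomputed, so the
returned alignment is always the unrestricted optimum while a 10,000-symbol
alignment stays in tens of milliseconds and a few tens of megabytes.

## Error classification and localization

`classify_errors()` converts the consensus map into one record per
discrepancy:

* symbol-over-gap columns are candidate deletions (bead imaged, missing on
  the plate); gap-over-symbol columns candidate insertions;
* adjacent complementary mismatches `(x,y)(y,x)` merge into one
  misplacement (a transposition);
* a candidate deletion and insertion of the same symbol within
  `pair_window` columns (default 10) merge into one misplacement — the bead
  left here and resurfaced there;
* leftover mismatches are misplacements; leftover candidates keep their
  class.

A gap inside a homopolymer run cannot be localized beyond the run: deleting
any `A` of `AAAA` yields the same sequence. The report therefore places gap
positions at the midpoint of the gap's *ambiguity region* — the maximal run
of the gapped symbol, extended through positions that are themselves gapped
in the same alignment (deleting the separator of two runs merges them into
one region). When several gaps share one region their reported positions are
spread at the rounded g-tiles `l + (r − l)(2i − 1)/(2g)`, which minimizes
the worst-case distance to any admissible true position. This matters
quantitatively: with three symbols, about 1 in 250 deletions falls in a run
of six or more identical symbols, where no ±2 window around any single
reported position can cover every admissible site.

`match_truth()` scores a report against simulation ground truth: a true
error is *detected* (localized) when some reported position lies within
`tolerance` symbols (default 2) of its true site — for misplacements, of
either the removal or the reinsertion site. Detection probabilities are
meaningless without the tolerance and the displacement model, so both are
carried in every `detection_curve` object.

## What detection probability the local misplacement model can reach

A misplaced symbol is invisible when every symbol it jumps over equals the
moved symbol itself: the corrupted sequence is then character-identical to
the template and no aligner can see the move. Under uniform symbol weights
the probability that a move of distance `d` is invisible is `(1/3)^|d|`;
averaging over the default offset distribution (uniform on ±1..±5),

    P(invisible) = (2/10) * sum_{d=1..5} (1/3)^d ≈ 0.099.

Misplacement detection under this model therefore plateaus near 0.90 at
*any* error rate — a property of the displacement model, not of the
detector. At a 5% misplacement rate the package measures ≈ 0.92 (boundary
effects and multi-error interactions add a little visibility), in line with
the figure reported for the original instrument; at 1% it stays near 0.90,
whereas near-total detection at low rates would require a longer-range
displacement process (`max_shift = Inf` behaves that way). Deletions are
always visible; their detection is limited only by localization ambiguity
and reaches ≈ 0.99 at both 1% and 5% rates with tolerance ±2.

## Drop rules, count verification and the mapping table

`match_segments()` applies the error-isolation policy. An inter-marker gap
survives only when its two flanking markers align as clean, column-adjacent
matches; then the imaged and plate cell counts of the gap are compared and
the gap is kept only on equality. Everything else is dropped with a recorded
reason: `dropped_marker_error` (a flank is involved in any reported error —
the conservative symmetric reading of "skip the cells following an
erroneous marker"; `drop_rule = "following"` implements the directional
reading and keeps the gap before a mismatched-but-present marker),
`dropped_count_mismatch`, or `dropped_flanking` (the gaps before the first
and after the last marker have no verifying pair and are always dropped).

`build_mapping()` pairs the i-th imaged cell with the i-th plate cell
within each matched segment and attaches plate coordinates
(`dispense_layout()` provides the serpentine grid of a robotic dispenser:
250 µm along the line of travel, 500 µm between lines). Out-of-focus cells
stay in the table with `usable = FALSE`. `retention_stats()` reports the
fraction of interior imaged cells mapped, the misassignment rate among them
(against ground truth), and the usable fraction.

The policy trades retention for safety, and one residual risk is
irreducible by design: a misplacement that stays *within* one gap preserves
both flanking markers and both counts while breaking the FIFO pairing
inside the gap. With ~2-cell gaps and local ±5 moves, roughly a third of
moved cells reorder within their own gap, so at a 1% misplacement rate
misassignment among retained cells sits near 1% while retention stays
around 85–90% at 1% + 1% combined rates. Only shrinking the gaps (more
markers) or a cell-level identifier would reduce it further; per-gap
counting cannot.

## Monte Carlo experiments

`detection_curve()` reproduces the sequence-level study: a fresh random
10,000-symbol template per replicate, corruption at each rate, alignment,
classification, truth matching; means and standard errors over replicates
(default 20 — enough for sub-percent standard errors at these rates).
`retention_curve()` runs the full pipeline (stream → corruption → encoding
→ alignment → drop rules → mapping) and averages `retention_stats()`.
Desk-scale defaults are deliberate: 10,000 symbols for detection (the
headline design), 1,000 markers / 2,000 cells per retention replicate;
the test suite uses smaller sizes (200–800 symbols) where only properties,
not headline values, are being checked. `scripts/acceptance.R` recomputes
the headline values from scratch.

## Synthetic plate images

`synth_plate()` renders what the low-resolution plate camera sees: objects
as anti-aliased bright disks (intensity 1), the membrane's pores as many
small dimmer disks (diameter drawn up to 5 µm, 200 per mm², intensity
0.45), plus additive Gaussian noise, at 2.5 µm/pixel by default. The
ground-truth layout is returned verbatim, so detection benchmarks are
self-contained.

`remove_pores()` blurs (σ = 1 px), thresholds (Otsu by default) and removes
every connected component whose *half-peak footprint* — the unblurred
pixels above half the component's peak intensity — has an equivalent
diameter of at most `max_pore_diameter` (default 9 µm, below the smallest
10 µm object). The half-peak criterion, rather than raw component area, is
what makes the size filter robust: when no bright object is present Otsu
settles between background and pores and the blur halo inflates pore
components well past their physical size, while the half-peak footprint
stays at the true ~5 µm scale; it is also invariant to overall intensity
scaling. `detect_objects()` returns intensity-weighted centroids (pixel-
center convention) and equal-area equivalent diameters;
`classify_by_size()` assigns classes from half-open diameter bands. Marker
bands default to A = [7,14), T = [16,24), C = [26,36) µm, but cells must be
given an experiment-specific band: real cell sizes overlap the bead sizes,
a limitation of size-only classification that synthetic fixtures sidestep
by using separable sizes (18 µm cells in the benchmarks).
`register_coordinates()` translates all coordinates so the first marker in
scan order (ascending x, then y) sits at (0,0), the convention of the
registration tables used to drive cell pickup; on the synthetic benchmark
plates the end-to-end localization error is well below a micron, far inside
the ±10 µm the pickup tools need.

## Morphometry and clustering

`features_2d()` (projected area, second-moment ellipse axes, two-direction
Crofton perimeter) and `features_3d()` (voxel volume, exposed-voxel-face
surface area) implement the tabulated per-cell features. Voxel-face surface
area is exact for axis-aligned solids — a 10³ cube gives exactly 1,000 µm³
and 600 µm² — and biased upward by a known factor (≈1.5 on a sphere); it is
kept because exactness on testable shapes and monotone behaviour matter
more here than absolute accuracy on smooth shapes. Six features are the
named tabulated set; eccentricity, extent, sphericity and 3D aspect ratio
are available behind `extras = TRUE` but off by default.

`kmeans_fit()` is a from-scratch Lloyd's algorithm with k-means++ seeding,
`n_init` restarts keeping the lowest inertia, and z-score standardization
stored in the model so `predict()` can apply the *fit-time* scaling to new
data — the fit-on-diseased-sample, predict-on-control workflow. Defaults:
k = 2 (the tabulated cluster labels are {1, 2}), 10 restarts, convergence
when the largest centroid shift drops below `tol`. Empty clusters are
revived with the farthest point; prediction ties break toward the lowest
cluster index; a degenerate all-identical input yields replicated centroids
with a warning. The choice of k and the identities of the five unnamed
features in the original eleven are not asserted — they are configuration.

## What the synthetic generators do not emulate

Passing tests on simulated data demonstrate the algorithmic properties —
optimal alignment, correct bookkeeping, the retention/misassignment
trade-off under the stated error model — not instrument performance. The
generators omit: timing (Poisson arrivals, coincident events), real
displacement distributions, correlated or bursty errors, cell/bead size
overlap, uneven illumination and focus gradients on the plate camera, and
segmentation of raw image stacks (masks are inputs here). Real-data figures
such as overall locatable-cell fractions depend on those factors and are
not reproducible at the desk; the package instead verifies every
mechanistic claim that is.

## Numerical conventions

* Coordinates and indices are 1-based everywhere; reported gap positions
  may be half-integers before rounding (midpoints of even regions are
  rounded to integers).
* Seeds: every stochastic function takes `seed` and restores the caller's
  RNG state; omitted seeds use the ambient RNG so callers can manage a
  single stream.
* Pixel-center convention: pixel (i, j) has its center at
  ((j − 0.5)·s, (i − 0.5)·s) µm.
* Degenerate inputs: empty sequences align to all-gap columns; streams
  without markers are encodable but refuse matching; empty masks are
  rejected by the feature extractors; `k > n` is rejected by the
  clusterer.
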