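---
title: "Fractal dimension, connectivity and cost in dendritic arbors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal dimension, connectivity and cost in dendritic arbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

CA1 pyramidal neurons collect synaptic input through dendritic arbors whose
branches fork and weave through the stratum radiatum and stratum oriens. Over
roughly one order of magnitude of length scales these arbors behave like
fractals, and a single *effective fractal dimension* `D` — the exponent of the
box-counting power law `N_box ~ L_box^-D` — summarizes how much fine-scale
structure the arbor packs relative to its coarse-scale envelope. A straight
wire has `D = 1`; a space-filling tangle approaches `D = 3`; traced basal and
apical arbors cluster near `D = 1.4`.

Why that value? A high-`D` arbor presents a larger *connectivity density* to
axons arriving from all directions, but it also costs more to build (branch
volume) and to operate (membrane surface, a proxy for ATP turnover). This
package implements the full measurement chain needed to chart that trade-off
on synthetic arbors:

* a centerline data model (SWC) with tube meshes (16-vertex rings, 32 side
  faces per segment, 14-face end caps) and Wavefront OBJ input/output;
* exact surface voxelization (separating-axis triangle/cube tests) and
  solid fills;
* 3D sliding box counting with the scaling-window rules used for traced
  neurons, and a max-R² straight-line fit over every sub-range spanning at
  least one decade;
* orientation-averaged profiles: the arbor is dilated by a 2 µm spine layer,
  orthographically projected from Fibonacci-lattice viewpoints, and the
  blocked (de-duplicated) shadow area `P` is averaged over orientations;
* convex-hull bounding area/volume (`A_b`, `V_b`), membrane area `A_s` with
  midpoint subdivision and buried-face exclusion, and branch volume `V_m`;
* angle manipulation: weave (`θ`) and fork (`φ`) angles are multiplied by a
  factor `α ∈ [0, 2]` through rigid subtree rotations, processed from the
  tips inward, with angles folded into [0°, 180°];
* generators for every study object: straight, weaving, and equal-branch-
  length H-trees, neuron-like toy arbors, and Euclidean fixtures.

The optimization statistics are the derivative ratios

$$R_{PA}(D) = \frac{\mathrm{d}(P/A_b)/\mathrm{d}D}{\mathrm{d}(A_s/A_b)/\mathrm{d}D},
\qquad
R_{PV}(D) = \frac{\mathrm{d}(P/A_b)/\mathrm{d}D}{\mathrm{d}(V_m/V_b)/\mathrm{d}D},$$

computed from third-degree polynomial fits of each metric against measured
`D` over an ensemble of arbors; their peaks mark the `D` at which additional
connectivity is bought most cheaply.

## Study objects and their defaults

**H-trees.** Branch lengths shrink by `L_i = L_1 / 2^{(i-1)/D}`; level *i*
holds `2^{i-1}` branches; fork angles are 90° and three-dimensional trees
rotate the branching plane by 90° about the parent axis at each level. The
defaults are 12 levels and a branch width of 1 µm. The total branch length is
held constant across `D` (the comparative analyses require it); its default
of 9000 µm was chosen so that `L_1` — the H-tree's maximal branch length —
falls inside the 109–352 µm range of maximal branch lengths reported for
traced CA1 arbors over the exponents of interest, which in turn keeps the
box-counting window (2 µm up to a fifth of the bounding box) wider than one
decade. Weaving H-trees subdivide each branch into width-long segments and
bend them by weave angles drawn from fractional Gaussian noise (exact
Durbin–Levinson synthesis) rescaled to a chosen standard deviation; the
Hurst exponent is not pinned down by the weave protocol, so it is exposed
with a documented default of 0.75. Weaving preserves arc length exactly.

**Toy arbors.** Random binary trees anchored to the median morphometrics of
the traced population: weave angles half-normal with median 12°, fork angles
folded-normal with median 37°, log-normal segment lengths (median 2.4 µm) and
branch widths (median 1.4 µm). Only the medians are anchored; these arbors
are stand-ins for reconstructions, not models of the full joint distribution.

**Euclidean fixtures.** Icospheres (refinement 4 is within ~0.2% of the
analytic sphere), solid voxel cubes and voxel lines bracket the analysis at
`D = 3` and `D = 1`.

## Numerical choices that matter

*Voxelization is conservative.* A voxel is occupied if any face touches its
cube. This "exact" rule inflates every silhouette by roughly half a voxel
diagonal, which matters for small objects: a radius-10 µm sphere voxelized at
1 voxel/µm measures an orientation-averaged `P/A_b` of ≈ 0.30 against the
analytic 0.25 (the shadow radius is ≈ 11 µm rather than 10), and its
direction-to-direction spread is ~10%. The bias shrinks like the
voxel-to-object size ratio and is shared by all arbors processed at the same
resolution, so comparisons across `D` are unaffected; absolute sphere
numbers at this scale are not.

*Box counting.* Boxes slide diagonally in 0.25 µm steps and the minimum count
is kept; the number of offsets is capped (64 by default; 16 in the large
ensembles, which changes fitted `D` by < 0.005 at 4 voxels/µm). Box sizes are
quantized to whole voxels — fractional sizes make voxels straddle partitions
and put a sawtooth on the curve. The admissible fit window for tube-like
arbors excludes boxes below 2 µm (where counts pick up the two-dimensional
character of the branch surfaces) and above a fifth of the bounding box
(where all boxes fill and the slope saturates at 3). For genuinely solid
fixtures that saturation *is* the signal, so solid objects are fitted over
the full curve; the ≥ 1-decade maximum-R² rule is the same everywhere.

*Volumes.* `V_m` is the volume of the union of segment cylinders measured by
strict center-in-cell counting on a lattice at twice the stated resolution
(overlapping segments count once). A plain count of covering voxels
overestimates a 1 µm tube by ~45% at 4 voxels/µm; the half-resolution
center rule is accurate to a few percent. Meshes without centerline
provenance (spheres, OBJ imports) are flood-filled from the grid boundary
and the cover enters with weight one half.

*Surface areas.* Each face is split into four midpoint sub-triangles (area
preserving); a sub-face is dropped only when all three vertices lie strictly
inside another segment's cylinder — ties count as outside, so coincident
surfaces are kept.

*Angle scaling.* The junction angle furthest from the soma is adjusted
first; each adjustment rigidly rotates everything between that junction and
the terminal tips in the plane of the two defining vectors, so downstream
angles and all lengths are preserved exactly, and the measured angle after
scaling equals `fold(α·θ)`. When both angle families are scaled, a single
inward sweep interleaves them in order of path distance. Scaled angles
beyond 180° fold back (200° measures as 160°); the crossing count is
reported. Self-intersections are permitted and counted, not repaired.

## What the measurements show on synthetic arbors

Across an ensemble of straight H-trees (`D_target` 1.02–1.7) and weaving
H-trees at four weave widths (σ = 10°–40°, strong weave paired with low
exponents so every tree keeps a one-decade scaling window), the package
reproduces the qualitative structure of the connectivity/cost trade-off:
`P/A_s` falls monotonically with measured `D`, while `A_s/A_b`, `P/A_b` and
`V_m/V_b` rise; near the low-`D` end `R_PA < 1` and `R_PV > 1`; both
derivative ratios peak at low `D` (R_PA near 1.35 on the default seed), close
to the `D ≈ 1.4` at which traced arbors cluster. The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch.

Two honest limitations surfaced by the same measurements:

* Box-counted `D` of a *finite* 12-level H-tree runs 0.1–0.3 above its
  generator exponent. An independent skeleton oracle (point-sampled
  centerlines, brute-force counts) shows ≈ +0.1 of this is the finite-level
  transient of the construction itself and the rest is tube-width blur at the
  fine end of the window. Measured `D`, not the generator label, is therefore
  used as the abscissa everywhere.
* A 12-level equal-branch-length `φ = 90°` H-tree is *not yet* space-filling:
  its branches collapse onto a walk lattice spanning only ~9 spacings per
  axis, so the slope-3 regime is shorter than one decade and the fitted
  dimension tops out near 2.6 (the asymptotic `D → 3` needs of the order of
  twenty levels, i.e. a million branches). The package reports the faithful
  measurement for the densest 12-level realization (branch length equal to
  the width).

## What the synthetic tests do not show

The generators emulate branch-length scaling, forking, weaving and the
stated median morphometrics — not boutons, spines as discrete objects,
tapering diameters, tissue boundaries, or the joint statistics of real
reconstructions. Passing tests demonstrate that the measurement chain is
correct and that H-tree ensembles reproduce the trade-off structure; claims
about the traced CA1 population (median `D` of 1.41/1.42, the equalization
drop to 1.30, the neuron `R_PV` peak at 1.32) require the deposited
reconstructions and are exposed through `check_neuron_population()` rather
than asserted by the test suite.

## Problem sizes used by the suite

The test-suite and acceptance runs use 12-level H-trees at 9000 µm total
length, box counting at 4 voxels/µm (2 voxels/µm in a few invariance
checks), 201 measurement viewpoints (10,001 for the convergence check), and
a 20-tree ensemble; these sizes keep every individual measurement to tens of
seconds while leaving the scaling windows wider than a decade.
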