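---
title: "Quantifying 3D microvascular architecture: methods and design notes"
author: "vasculometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D microvascular architecture: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculometry)
```

## The measurement problem

High-resolution volumetric angiography (synchrotron micro-CT of
contrast-perfused tissue, at a few micrometers per voxel) resolves a
vascular network down to near-capillary scale: with 3.7 um pixels the
smallest resolvable tube is one voxel in radius, i.e. about 7.4 um in
diameter. Quantifying how that network changes -- after a spinal cord
contusion, for example -- requires reducing the gray-level volume to a small
set of morphometric numbers:

* **VV**, vessel volume: the fractional occupancy of segmented vessel
  voxels in a region of interest (also expressed in cubic millimeters);
* **VN**, vessel number: the number of vessel segments between nodes of the
  vessel tree;
* **VNN**, vessel node number: the number of bifurcation points;
* **VD**, vessel diameter: twice the centerline radius, averaged along each
  segment;
* **theta**, the signed intersection angle between a branch (e.g. a central
  sulcal artery) and the rostrally-oriented trunk axis (the anterior spinal
  artery): positive when the branch points rostrally (at most 90 degrees by
  construction), negative when it falls back caudally.

The pipeline implements the standard chain for this reduction: iterative
gray-level thresholding, a 3D size filter, a Euclidean distance map (EDM),
topology-preserving thinning to a one-voxel centerline, and conversion of
the centerline into a graph of nodes and segments.

```{r pipeline, eval = FALSE}
cfg <- defaultRunConfig()
res <- runPipeline(cfg, outDir = "run1", seed = 1)
res$report
```

## Why a synthetic phantom is first-class here

Scan data of this kind are rarely redistributable, and no public volume
accompanies the measurements this package reproduces. Every stage is
therefore validated against a synthetic angiography phantom whose ground
truth is known *exactly*: a bifurcating tube tree (a longitudinal trunk
that splits into progressively thinner lateral branches, echoing the
central-sulcal blood supply pattern of the cord) is rasterized onto the
voxel grid, degraded with partial-volume blur and additive noise, and then
pushed through the same pipeline a real scan would take. Recovered VN, VNN,
VD and theta can then be compared against the generator's record.

The phantom emulates: tube-like bright structures of 7.4-100 um diameter on
a darker parenchymal background, 3.7 um isotropic sampling, partial-volume
smoothing at the voxel scale, additive Gaussian noise at a
contrast-to-noise ratio of 5, and an injury state (below). It does *not*
emulate: gray/white-matter texture, beam-hardening or reconstruction
artifacts, vessel curvature or caliber variation along a segment,
anastomoses (the truth is a tree), or contrast-filling failures. Passing
the phantom suite therefore demonstrates the correctness of the chain on
clean tubular geometry plus stationary Gaussian noise -- not robustness to
every artifact of real tomograms.

### Generator parameters (defaults in parentheses)

* `gridShape` (128^3 voxels) and `spacingUm` (3.7 um isotropic) match the
  sampling scale of the target instrument class.
* `trunkRadiusUm` (18.5 um = 5 voxels): a mid-caliber trunk, comfortably
  above the detection floor yet small enough that branch tapering stays in
  range.
* `branchLevels` (2) with two children per node: 1 + 2 + 4 = 7 segments and
  3 bifurcations, the smallest tree that exercises junctions at more than
  one depth.
* `branchAngleDeg` (45) with seeded uniform jitter `angleJitterDeg` (5):
  reproducible but non-degenerate geometry; children alternate sides, and
  the rotation plane alternates with depth so the tree spreads in 3D.
* `taperRatio` (0.8): child radii 14.8 and 11.84 um -- all within
  `radiusRangeUm` (3.7-50 um, diameters 7.4-100 um).
* `foregroundIntensity` (200), `backgroundIntensity` (50), `noiseSigma`
  (30): contrast-to-noise (200 - 50) / 30 = 5. No noise statistics are
  published for the instrument class, so sigma is fixed once from the CNR
  the validation targets, not tuned per experiment.
* `blurSigmaUm` (3.7): one voxel of partial-volume smoothing.

The trunk is snapped to a voxel-centered transverse position. This is
deliberate: an axis-aligned tube whose centerline falls exactly between
voxel centers has no central voxel column, and *no* grid-thinning algorithm
produces a stable medial axis for it (reference implementations annihilate
such tubes entirely). Real vessels are never perfectly axis-aligned, so the
degenerate case is an artifact of synthetic geometry, and the generator
avoids manufacturing it.

### The injury model

Contusive injury is modeled as (i) a prolate ellipsoidal avascular cavity,
elongated along the cord axis (the "spindle" shape of real lesions), whose
enclosed vessels are deleted and crossing vessels truncated at the cavity
wall; and (ii) a signed tilt of branches near the epicenter -- rostral
branches displaced rostrally, caudal branches caudally -- emulating the
reported displacement of surviving sulcal arteries. The ground-truth graph
is edited first and the volume re-rasterized from the edited graph, so
graph and volume stay exactly consistent (warping the volume instead would
decouple them).

The default cavity (semi-axes 70 x 70 x 110 um, centered on the first
level-1 branch) engulfs one sulcal subtree. That choice follows the
biology: reported injury effects are a *decrease* in VN and VNN, which only
happens when whole branches are destroyed. A cavity that merely nicks
vessels *fragments* them and can increase the segment count -- a real and
somewhat counterintuitive property of cavity injuries that the test suite
exercises explicitly. The default tilt (19 degrees) mirrors the scale of
angular displacement reported for surviving branches.

## Stage-by-stage notes

### Segmentation

The threshold is the Ridler-Calvard (isodata) fixed point: starting from
the global mean, `T` is repeatedly replaced by the average of the means of
the two classes it separates until the update falls below a tolerance (0.5
gray levels for integer data -- which guarantees termination on quantized
images -- else 1e-4 of the intensity range). "Iterative gray-level
threshold" in the imaging literature is this algorithm; it is also what the
common ImageJ default implements.

Isodata has a known failure mode that matters for angiography: when the
foreground fraction is very small, the iteration can be captured by a
second fixed point that merely splits the background mode in half. On a
noisy volume with ~0.2% vessel voxels the captured threshold labels half
the parenchyma as vessel. Denoising before thresholding widens the escape
basin dramatically, so the *pipeline* applies a Gaussian pre-smoothing of
1.5 voxels (5.55 um) before the threshold by default
(`segmentation$presmooth_sigma_um`); with it, recovery of the default
phantom's topology is exact in 97% of seeds, and the threshold lands
between the modes even for the sparser injured phantoms. The
`isodataThreshold()` function itself performs no smoothing -- the operation
stays pure -- and on noise-free phantoms the unsmoothed threshold recovers
the rasterized truth mask exactly.

The size filter removes 26-connected foreground components and fills
6-connected background cavities smaller than three voxels. "Smaller than
three" is read strictly: components of exactly three voxels survive. The
26/6 connectivity pairing is the standard dual that avoids topological
paradoxes; the filter's connectivities are configurable.

### Distance map and radii

The EDM is computed with the separable lower-envelope algorithm, which is
*exact* for Euclidean distance and honors anisotropic spacing; the test
suite checks exact agreement with an O(n^2) nearest-background search. The
historical chamfer (3,4,5) approximation is available behind a flag for
fidelity comparisons with legacy chamfer-map outputs (isotropic spacing
only), but the exact transform is the default because the quantity of
interest is defined as the true distance to the background. Per-voxel radii
are the EDM values on the skeleton ("skeleton times EDM"); a radius-5-voxel
cylinder reads out VD = 37 um at 3.7 um spacing, and the one-voxel tube
reads the 7.4 um floor.

### Thinning

Centerlines come from iterative deletion of *simple points* -- voxels whose
removal changes neither the 26-connected foreground components nor the
6-connected background components locally (checked by the standard
two-condition neighborhood characterization) -- in six directional
subiterations, deleting sequentially with re-validation so topology
preservation is exact, and never deleting curve endpoints. The subiteration
order is fixed at (N, S, E, W, U, D): eroding the transverse directions
before the longitudinal ones keeps the medial axis of near-axial tubes
centered (the U/D-first order systematically displaced the axis of a
radius-5 cylinder by one voxel, biasing VD by ~17%). Determinism of the
output is part of the contract.

No spur pruning is applied by default; `pruneSpurs()` (or
`skeleton$prune_length_um` in the pipeline) is available when noisy data
produce short endpoint branches.

### From skeleton to vessel tree

Skeleton voxels are classified by their number of skeleton neighbors
(1 endpoint / 2 slab / >= 3 junction). Thinning produces junction
*clusters*, not single junction voxels; 26-connected junction voxels are
merged into one node at their centroid, because counting them individually
would inflate VNN. Segments are traced through slab voxels between nodes in
raster-scan order (deterministic); node-free cycles are retained as
cyclic segments and flagged, so a looped skeleton yields VN = 1, VNN = 0
rather than disappearing. Segment length is the spacing-aware polyline arc
length. VD is twice the mean skeleton radius along the segment, excluding
the two voxels nearest each end when the segment is long enough (> 6
voxels), because the EDM is inflated where tubes merge.

### Bifurcation angles

A branch direction estimated from single voxel steps is quantized to the
26 lattice directions, so directions are principal-axis fits over several
voxels. Two design points matter:

* Skeleton voxels within one local vessel radius of the junction centroid
  are *skipped* before the fit. Inside that zone the centerline runs
  through the merged blob of parent and child tubes and shortcuts, biasing
  shallow angles steeply upward (a 30-degree branch read as ~55 degrees
  when fitted from the first five voxels). With the skip, angles of
  30-90 degrees are recovered within ~2 degrees on rasterized phantoms.
* The fit window is k = 10 voxels past the skipped zone (configurable).
  Branches with fewer usable voxels are omitted with a warning rather than
  reported badly.

The sign convention follows the anatomy: theta is measured against the
rostrally-oriented trunk axis, reported positive (<= 90 degrees) for
rostrally-pointing branches and as the negative supplement for caudal ones.

### Statistics

Group summaries are mean +/- sample SD. The two-arm comparison uses the
two-sided pooled-variance Student's t-test (Welch's correction behind a
flag), one test per metric with *no* multiple-testing correction across
VV/VN/VNN/VD -- this mirrors the reporting convention of the experimental
literature the package serves and is a documented limitation, not an
oversight. Degenerate inputs are handled explicitly: identical constant
arms give t = 0, p = 1; constant arms with unequal means make the statistic
undefined (error from `twoSampleTTest()`; `compareMorphometry()` reports
the means with NA test columns so the rest of the table survives).

## Numerical conventions

* Voxel-center convention: physical position = 0-based index x spacing;
  axes are (x, y, z) with +z rostral.
* Rasterization includes a voxel iff its center is *strictly* within the
  tube radius, with a 1e-12 relative tolerance excluding centers exactly on
  the wall symmetrically. Exact-integer-voxel radii are common in phantoms
  (18.5 um = exactly 5 voxels), and letting floating-point rounding decide
  wall membership produced asymmetric tubes with off-center skeletons. The
  strict convention also makes "radius of one voxel" mean a single-voxel
  column, which is the sensible reading of the detection floor.
* ROIs are half-open boxes `[lo, hi)` on every axis, so tiling ROIs
  partition a volume exactly; segments touching the ROI are counted without
  edge correction (documented, configurable only by changing the ROI).
* Histogram bins for the diameter distribution are half-open `[a, b)`,
  counted per segment, not per voxel.
* Anisotropic volumes are thinned on the voxel grid (topology ignores
  spacing); distances and lengths always honor spacing. This is a
  documented limitation for strongly anisotropic data.

## Validation problem sizes

The shipped tests and the acceptance script use: 50 random masks up to
20^3 voxels for exact EDT checking; a fixture suite (cylinder, Y-tube,
torus, disjoint tubes) for topology preservation; the default 128^3
seven-segment phantom, noise-free (exact VN/VNN recovery) and at CNR 5 over
20 seeds (mean VN/VNN within 10%); 96-voxel-cube single-branch phantoms at
30/45/60/90 degrees for angle recovery; 5 + 5 phantom arms for the
injured-vs-normal contrast; and 500 null simulations for the t-test's
type-I error. These sizes were chosen as the smallest that exercise each
property convincingly on a desktop machine.

## Known limitations

* The tree phantom contains no loops; cyclic-vessel handling is tested on
  hand-built skeletons and the torus fixture only.
* VD along a segment assumes a locally circular cross-section, as the
  EDM-radius definition does.
* Isodata thresholding on extremely sparse foregrounds (< ~0.1% after
  denoising) can still be captured by the background mode; inspect the
  threshold history (`ThresholdResult`) when segmenting unusual data, or
  pass a fixed threshold.
* The angle estimator requires branches at least `skip + k` skeleton voxels
  long; very short branches yield no angle.
* Real tomographic artifacts (rings, beam hardening, motion) are outside
  the phantom's noise model and untested.
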