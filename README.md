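# vasculometry

Quantitative 3D morphometry of microvascular networks in volumetric
angiograms — the image class produced by synchrotron micro-CT of
contrast-perfused tissue, e.g. rodent spinal cord, at a few micrometers per
voxel. The package is aimed at researchers who need the standard vascular
read-outs from such volumes and a way to *validate* the measurement chain
without access to raw beamline data.

## What it computes

Given a grayscale volume, the pipeline produces the vessel-tree model and
its morphometric parameters:

* **VV** — vessel volume: fractional occupancy of the segmented
  vasculature in a region of interest, and the same volume in mm³;
* **VN** — vessel number: count of centerline segments between nodes of
  the vessel graph;
* **VNN** — vessel node number: count of bifurcation nodes;
* **VD** — vessel diameter per segment: `VD = 2·r̄`, twice the mean
  centerline radius, where the radius at a skeleton voxel is its Euclidean
  distance map (EDM) value — the distance to the nearest background voxel;
* the per-segment length **L** and the **diameter distribution** (segments
  per diameter bin);
* **θ** — the signed branch–trunk intersection angle: against the
  rostrally-oriented trunk axis, `+θ ≤ 90°` for branches pointing
  rostrally, `−θ` for branches falling back caudally.

The chain is: iterative gray-level (isodata/Ridler–Calvard) thresholding
`T_{k+1} = (mean(I ≤ T_k) + mean(I > T_k))/2`, a 3D size filter that
removes foreground/background structures smaller than three voxels, an
exact Euclidean distance transform, topology-preserving 3D thinning
((26, 6) digital topology, simple-point deletion), and centerline-to-graph
conversion with junction-cluster merging.

Because raw scans of this kind are rarely shareable, the package includes a
first-class **synthetic phantom generator**: seeded, bifurcating tube trees
with exactly known geometry (plus a spindle-shaped cavity/displacement
injury model), so every stage can be verified against ground truth. All
voxel-level cores (distance transform, thinning, connected components,
tube rasterization, separable Gaussian filtering) are implemented in C++
via Rcpp.

## Worked example

Generate the default phantom (128³ voxels at 3.7 µm, a 7-segment vessel
tree at contrast-to-noise 5) and push it through the pipeline:

```r
library(vasculometry)

ph   <- generatePhantom(phantomSpec(seed = 1))
seg  <- segmentVolume(ph$volume, presmoothSigmaUm = 5.55)
seg$threshold
#> ThresholdResult: T = 92.7151 after 14 iterations

mask  <- seg$mask
edm   <- euclideanDistanceMap(mask)
skel  <- skeletonize3D(mask)
graph <- buildVesselGraph(skel, radiusFromEDM(skel, edm))
summarizeROI(mask, graph)
#> MorphometryReport
#>   VV: 0.006259 (fraction), 0.000664871 mm^3
#>   VN: 7   VNN: 3
```

The isodata threshold (92.7) lands between the parenchyma (50) and vessel
(200) modes of the noisy volume; the graph recovers the phantom's true
topology exactly — 7 segments, 3 bifurcations. Per-segment geometry:

```r
graphSegments(graph)[, c("id", "from", "to", "length_um", "diameter_um")]
#>   id from to length_um diameter_um
#> 1  1    4  1 181.30000    39.87984
#> 2  2    1  2 128.38439    33.24595
#> 3  3    1  3 124.04957    33.15547
#> 4  4    2  5  86.17966    25.50063
#> 5  5    2  6  79.95566    25.79618
#> 6  6    3  8  93.93625    25.80720
#> 7  7    3  7  88.88825    25.41473

bifurcationAngles(graph)
#>   segment node theta_deg
#> 1       1    1   0.00000
#> 2       2    1  49.56509
#> 3       3    1  45.00000
#> ...
```

Segment 1 is the trunk (θ = 0°, measured VD 39.9 µm for a true diameter of
37 µm under noise); the level-1 branches read 45.0° and 49.6° against
ground-truth angles of 45° ± 5° jitter. The same run as a single call, with
artifacts (mask, skeleton, EDM, radius map, GraphML/JSON graph, CSV tables,
provenance record) written to disk:

```r
res <- runPipeline(defaultRunConfig(), outDir = "run1", seed = 1)
```

An injured cohort only needs `cfg$injury$enabled <- TRUE`; the cavity
destroys one sulcal branch subtree, and `compareMorphometry(normal,
injured)` produces the two-arm mean ± SD table with pooled t-tests.

Volumes read/write as multi-page TIFF (8/16-bit, spacing in a JSON
sidecar), NIfTI (spacing in the header), or raw + JSON sidecar; masks on
disk are 8-bit with 0 = background, 255 = vessel. A thin CLI over the same
functions ships in `inst/scripts/vasculometry.R` (subcommands `run`,
`phantom`, `segment`, `skeletonize`, `morphometry`, `compare`).

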