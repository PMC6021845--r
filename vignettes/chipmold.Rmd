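---
title: "From color-coded blueprints to printable chip molds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From color-coded blueprints to printable chip molds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipmold)
```

`chipmold` converts a 2D color-coded blueprint of a Lab-on-a-Chip master
template into a printable STL mold and quantifies (a) how faithfully two such
molds agree in top view and (b) how visible a striped growth marker remains
through culture broth. This vignette records the model behind each stage, the
parameters that matter, and the design decisions that were genuinely open.

## 1. Blueprint classification

A blueprint is a small raster image in which color encodes structure. The
default palette follows the conventional code — white makes only the base
slab, black a channel, red a culture chamber, yellow a small syringe port and
blue a large tubing port. Published practice names these roles but no numeric
extrusion heights, so heights are a configuration surface; the defaults
(channel 1, chamber 2, small inlet 3, large inlet 5 voxel layers) are
deliberately ordered so ports are deeper than chambers and chambers deeper
than channels, matching what tubing and syringe ports need in cast PDMS.
Exact RGB primaries are assumed for the role colors; both colors and heights
can be replaced via `palette_spec()` or a YAML file.

Classification assigns each pixel the role of the nearest palette color in
raw-RGB Euclidean distance, accepting the match only within a tolerance
(default 32, guarding against anti-aliasing halos). The palette validator
requires the tolerance to be under half the minimum pairwise color distance,
which makes classification unambiguous; ties (possible only at exactly equal
distances) go to the earlier palette entry, so results are deterministic and
independent of the ordering of non-tied entries. In strict mode (default) an
unmatched pixel aborts with its coordinates; lenient mode maps it to base and
counts it.

Resizing to the working resolution (longest side ≤ 150 px by default, a
practical bound for hand-drawn input) uses nearest-neighbor sampling only.
Any interpolating filter would manufacture out-of-palette colors along
feature edges; nearest-neighbor provably returns a subset of the input
colors, so a palette-valid image stays palette-valid, and resizing at a fixed
bound is idempotent.

## 2. Scale model

Physical scale is one ratio: `mm_per_pixel = target_size_mm / pixels`. A
30 mm mold drawn at 150 px gives 0.2 mm blocks, and a 10 px channel then
prints 2 mm wide. The ratio is held exactly (no rounding); all mesh
coordinates are integer lattice positions times this scalar, which keeps
volume and overlap checks exact.

## 3. Heightmap extrusion

Each pixel becomes one voxel column: `base_layers` slab voxels (default 2 —
the slab must exist everywhere but its thickness is a free choice) plus the
role height. Because every column is solid from `z = 0`, the grid is fully
described by its column-height matrix; `chipmold` stores exactly that, and
materializes the boolean occupancy array only on demand. The persisted grid
container (versioned magic header, dimensions, voxel size, int32 heights) is
therefore bit-exact under round trip. Columns being contiguous is also what
the surface extraction exploits below. The vertical limit defaults to 256
voxels for compatibility with common voxel tooling and is configurable
upward; the supported envelope is checked by `grid_capacity_check()` and the
pipeline is routinely exercised at 1000 × 1000 × 120.

Whether a blueprint should extrude as filled columns or as hollow walls is
not dictated by the drawing itself; filled extrusion over a base slab is
assumed, since a PDMS master is a positive-relief part.

## 4. Watertight surface extraction

The mesh consists of exactly the exposed voxel faces — faces between an
occupied voxel and an empty or out-of-bounds neighbor — each emitted as two
triangles with counter-clockwise outward winding and welded on shared lattice
vertices. Per-face emission (no greedy merging) is the reference path:
correctness and auditability first. The enclosed volume then equals
`occupied_voxels × s³` identically, which every mesh-producing test checks
against the independent counting formula.

One configuration needs care: a *checkerboard corner*, where two diagonally
adjacent columns both rise strictly above both anti-diagonal neighbors. The
exact voxel surface is then non-manifold along the shared vertical edge (four
wall quads meet). Shared-vertex triangulations of that surface cannot make
every undirected edge 2-incident, so `grid_to_mesh()` performs a coplanar
subdivision: the two wall quads of one designated diagonal column are
fan-triangulated with the pinch-edge midpoint inserted. The two solids then
meet along collinear but combinatorially distinct edges; every undirected
edge in the result is shared by exactly two oppositely-oriented triangles, no
vertices are duplicated, no zero-area triangles appear, and the volume is
unchanged. The cost is a T-vertex on the pinch line — geometrically sealed
(the sub-edges are collinear with the full edge) and invisible to slicers.
`validate_mesh()` checks closedness, edge-manifoldness, orientation
consistency, degenerate triangles and volume; the property suite runs it on
randomized height fields where pinches occur naturally.

STL is written with the model's minimum corner at the origin and the flat
base on `z = 0` — the "backdown" orientation that minimizes print height and
keeps the flat face on the build plate. Binary records are the mandated
80-byte header, uint32 count, and 50 bytes per triangle (float32 normal and
vertices, zero attribute); internal math is double precision, with float32
only at the binary boundary. Normals are recomputed from winding on read;
stored normals are never trusted.

## 5. Top-view overlap statistic

Two molds are compared in top view. A pixel is *structure* when its column
rises above the base slab. The **error region** `E` is the symmetric
difference of the two structure masks ("non-overlapping regions" — counted
in either direction, since either a missing or a spurious structure pixel is
a disagreement); the **total region** `T` is the full rectangular base, and

* area error rate = `E/T`, area accuracy `A = 1 − E/T`;
* length error rate `r = 1 − √A`, length error `L = r·D` over the model
  diagonal `D`.

The square-root step treats the area accuracy as the square of a per-axis
scale factor: if each axis is reproduced to a fraction `1 − r`, the
reproduced area fraction is `(1 − r)²`. A literal linear reading of the area
ratio does not reproduce published worked values of this statistic, while the
square-root reading does to about 0.1%; the relation `(1 − r)² = A` holds by
construction and is asserted in the tests. Reports retain unrounded values
and print at 3 decimals.

Mesh inputs are rasterized by sampling column occupancy at pixel centers
(highest up-facing triangle covering the center), on a shared grid over the
union bounding rectangle. With `pixel_size_mm` equal to the source voxel
size, rasterizing a grid-born mesh recovers its mask exactly — pixel centers
fall at half-integer lattice positions, never on triangle edges. No
registration is attempted: the comparison assumes pre-aligned models, and a
deliberate k-pixel shift shows up as exactly the brute-force XOR band.

## 6. Marker visibility statistic

Bacterial growth is read out by photographing a striped marker behind the
culture chamber: turbidity blurs the stripes. "Counting nonzero pixels of
the FFT image" is only meaningful for a *displayed* spectrum — a raw digital
photograph's spectrum is almost nowhere exactly zero — so the displayed-image
interpretation is adopted and frozen as:

1. 2D FFT of the grayscale image (luma weights for RGB; no window by
   default, since the stripes are the dominant periodic signal — a Hann
   option exists);
2. centered magnitude; DC and a disk of radius 2 bins excluded;
3. display log mapping `L = log1p(255·m/m_max)/log1p(255)` — exactly
   invariant under intensity scaling of the input, unlike a bare
   log-magnitude;
4. 8-bit quantization, then count of bins above threshold 0.5.

Visibility is the count divided by the pre-culture count; the published
endpoint (count 1 against a starting 63) gives 0.0159, printed 0.02. For the
synthetic square-wave marker the analytic picture is simple: the spectrum is
a comb of odd harmonics, Gaussian blur of width σ multiplies it by a
decreasing Gaussian envelope, so harmonics drop below threshold one by one
and the count is nonincreasing in σ. With the default 128 px marker at
period 8, only two harmonic pairs exist below Nyquist, so counts move in
small steps (4 → 2); real marker photographs have much richer spectra and
correspondingly finer-grained counts (tens at the start of culture). The
statistic's *ratio* and its monotone decline are the normative behavior; the
absolute counts of any particular camera pipeline are not reproduced here.
One cautionary note: a photograph dominated by broadband sensor noise has a
flat spectrum whose count is *large* under any max-normalized statistic —
the metric presumes turbidity (smoothing), not noise, is what degrades the
image, which is the physical situation in a culture chamber.

## 7. Synthetic data

`generate_blueprint()` draws four parametric designs (growth chip with two
chambers, multi-width channel, two- and three-inlet serpentine mixers) using
only palette colors, and records per-role pixel counts that downstream tests
use as independent oracles. The layouts imitate the topology of hand-drawn
chip blueprints — ports, channels, chambers in realistic proportion — not
any specific device's coordinates. They are deterministic; randomness is
confined to marker noise and blueprint perturbation, both seeded and
RNG-state-preserving. `perturb_blueprint()` toggles exactly `n` pixels
across the base/non-base divide, so an overlap comparison of the original
and perturbed molds must report an error region of exactly `n` — a sharp
end-to-end oracle.

What passing these tests does *not* show: real blueprints are photographed
or scanned (anti-aliasing, uneven white balance), real molds come back from
a printer with resolution- and shrinkage-induced deviations, and real marker
photos contain lens blur and exposure drift. The synthetic generators model
none of these; they validate the pipeline's arithmetic, not a printer.

## 8. Numerical choices and problem sizes

* Classification distance in raw RGB (no perceptual space): reproducible and
  sufficient for the widely separated palette primaries.
* All mesh arithmetic on integer lattice coordinates scaled once by
  `mm_per_pixel`; volume checks exact to double precision, and to float32
  precision after an STL round trip.
* Rasterization tolerance `1e-4` of a pixel on point-in-triangle tests;
  irrelevant for aligned grid meshes (centers are interior), present for
  robustness on foreign meshes.
* Degenerate triangles flagged below `1e-12` of the bounding-box diagonal.
* Test problem sizes: property sweeps on grids up to 7×7×6 voxels (where
  exhaustive neighbor enumeration is the oracle), end-to-end conversions at
  150 × 100, and the capacity exercise at 250 × 250 with 120-voxel columns
  plus grid construction at 1000 × 1000 — sizes chosen to keep the default
  suite fast while covering the supported envelope; the full 1000 × 1000
  × 120 mesh extraction runs in well under a minute on one core.

## 9. Known limitations

* No mesh decimation or greedy face merging; files are larger than an
  optimized exporter would produce (the 1000² capacity mesh is ~4.4M
  triangles). Slicers handle this without difficulty.
* No vector blueprint input, no auto-registration before overlap comparison,
  no OD600 conversion of visibility (calibration data for that mapping is
  instrument-specific).
* JPEG and BMP rasters are not read; PNG (recommended for blueprints, as
  lossless) and TIFF are.
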