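---
title: "Refining volumetric prostate segmentations with a 3D statistical shape and appearance model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining volumetric prostate segmentations with a 3D statistical shape and appearance model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(prostasm)
```

## The problem and the model

Volumetric convolutional networks segment the prostate gland in T2-weighted
MRI with good global accuracy but imperfect boundaries: predictions carry
boundary jitter, holes and occasional detached blobs, and nothing in a
purely voxel-wise decision guarantees an anatomically plausible shape.
`prostasm` implements the complementary, model-based half of a hybrid
pipeline: an iterative 3D active shape model (ASM) that deforms a
statistical shape prior toward local image evidence, starting from any
coarse initial segmentation.

The prior is a classical point distribution model. Every training gland is
represented by a fixed-length list of K corresponded surface vertices
`x = (x_1 ... x_K)`; after alignment, PCA gives the mean shape `x_mean`,
the eigenvector matrix `Ws` and eigenvalues `lambda_s`, truncated at 98% of
total variance. Any plausible shape is `x = x_mean + Ws b` with each
coordinate bounded, `|b_i| <= m * lambda_i`. Image evidence enters through
gray-level profiles of length `2*ns_model + 1` sampled along the outward
surface normal at each vertex; their PCA (`g_mean`, `Wg`, `lambda_g`)
defines the appearance cost

    f(g) = sum_i (bc_i / lambda_g_i)^2,   bc = Wg' (g - g_mean),

which is zero for the mean profile, grows with eigenvalue-scaled deviation
along each appearance mode, and ignores deviations outside the model span.
Each ASM iteration (1) recomputes normals from the current shape's surface
triangulation, (2) slides every vertex to the profile position minimising
`f` within `±ns_search` samples, (3) aligns the moved shape to the model
frame, (4) clamps its `b` coordinates, and (5) restores the pose. The
clamping is what converts noisy per-vertex evidence into a globally
plausible gland.

Two conventions follow the source material deliberately even though the
classical ASM literature differs: the appearance cost divides by the
eigenvalue (not its square root), and the shape constraint bounds `|b_i|`
by `m * lambda_i` (not `m * sqrt(lambda_i)`). Both are the package default
(`eigen_scaling = "linear"`); the classical Mahalanobis forms are available
with `eigen_scaling = "sqrt"`. Similarly, the ablation presets ASM-1..ASM-4
follow the published configuration table verbatim (ASM-2 has `m = 1`
there), while the package default `asm_config()` follows the accompanying
text's best configuration (iterations 2, search length 8, constraint 2);
the two disagree in the source and neither is silently corrected.

## Correspondence extraction

Corresponded vertices are produced geometrically, without landmarking:

1. The mask (resampled to the 0.5 mm isotropic working grid) is fitted
   with an axis-aligned ellipsoid. The default estimator is moment-based —
   centre of mass plus semi-axes `r_i = sqrt(5 * var_i)`, exact for a solid
   ellipsoid — because it integrates over the whole gland and is therefore
   insensitive to boundary voxelisation. The algebraic surface fit
   (`method = "surface-ls"`) is retained for comparison; its radii estimates
   move by a few tenths of a millimetre under sub-voxel grid shifts, and the
   focal-distance construction below amplifies that noise into the ray
   sources.
2. Key reference points are derived from the fit: `F_xy = centre ±
   (c_xy/2) e_y` with `c_xy = sqrt(radius_max^2 - radius_min^2)` (the focal
   distance, radii sorted globally) and `F_xz = centre ± (c_xz/2) e_x` with
   `c_xz = radius_min`. The exponents in the source formulas are
   typographically ambiguous; this dimensionally consistent reading is a
   declared choice and both quantities are exposed on the fit object.
3. Surface voxels (deterministically thinned to `max_surface_points`,
   default 1500) are triangulated with a 3D alpha shape, `alpha = 50` mm.
4. Rays are cast from the five sources (centre plus the four key points)
   along a fixed fan — 8 azimuths at 45° steps crossed with 7 elevations
   from −67.5° to +67.5° — and the farthest ray–mesh intersection per ray
   (Möller–Trumbore) becomes a vertex. Ordering is (source, elevation,
   azimuth)-lexicographic, so K = 5 × 8 × 7 = 280 for every shape and
   vertex k corresponds across subjects.

Alignment removes translation (centroid match) and corrects rotation in two
planar Procrustes steps, each a four-quadrant inverse tangent: about z from
the x–y coordinates, then about y from the x–z coordinates. Similarity
scaling is deliberately omitted (a config-level choice; the source pipeline
aligns pose only). The farthest-hit rule also resolves multiple
intersections in the post-processing slicer; ties break toward larger ray
parameter.

## Appearance model and DBSCAN filtering

Profiles are sampled with cubic (Catmull–Rom) interpolation at one
isotropic voxel (0.5 mm) per step, `ns_model = 2`, giving length-5 profiles
centred on the surface and ordered inside → outside. Before PCA, profiles
from the whole training cohort are z-normalised and filtered with classic
DBSCAN (Euclidean distance, `min_pts = 8`, `eps` from the elbow of the
sorted k-distance curve unless given); the largest cluster survives, noise
points and minor clusters are dropped. Appearance statistics are kept
per-vertex (classic ASM practice) with a pooled-cohort fallback wherever a
vertex retains fewer than 3 inlier profiles; pooling across vertices versus
per-vertex statistics is genuinely undetermined in the source, so both
exist and the default is the per-vertex form.

## The phantom generator

The generator exists so every stage is testable without patient data. It
emulates: the acquisition geometry (default grid 96 × 96 × 24 voxels at
1 × 1 × 3 mm — thick axial slices at desk scale), a smooth simply connected
gland (an ellipsoid with semi-axes 20/17/15 mm deformed by degree-1/2 real
spherical-harmonic radial displacements), distinct interior/exterior
intensity distributions (N(150, 12) vs N(70, 12)), a smooth multiplicative
bias field (random quadratic rescaled into [0.9, 1.1]) and additive
Gaussian noise (sd 8). Corrupted initialisations mimic network output with
three seeded damage processes: spatially correlated boundary displacement
(a smooth unit-variance field added to the signed distance, amplitude
9 × severity mm — calibrated once so severity 0.3 lands in the 0.75–0.95
DSC band), Poisson-count interior hole punching, and up to two spurious
exterior blobs.

It does **not** emulate MRI physics (no Rician noise or coil profiles), no
neighbouring organs with confusable intensities, no apex/base ambiguity,
and its bias fields are polynomial. Passing tests therefore demonstrate the
correctness and internal consistency of the geometry, statistics and search
machinery — not clinical-grade accuracy on real cohorts, which requires the
original imaging data and a trained network.

Cohort shape variability defaults to two active modes with a 3:1 amplitude
ratio: the degree-2 tesseral harmonics in y–z (sd 1.5 mm) and x–z (sd
0.5 mm). Two properties motivated this choice, measured during design:
moment-coupled modes (e.g. z-elongation) move the ellipsoid-derived ray
sources with the mode weights, giving the corresponded vertices a quadratic
response that PCA sees as spurious extra modes; and amplitudes much above
~2 mm RMS leave the linear-response regime of the fixed-fan correspondence
operator. Within that regime the recovery experiment is well-posed: 30-shape
cohorts retain exactly the two generating modes at 98% variance and the
leading eigenvector correlates with the generating displacement field at
|r| > 0.95. Mode-recovery cohorts are generated directly on the 0.5 mm
isotropic grid: the 3 mm slice terracing of the acquisition grid alone
contributes ~0.24 mm of systematic vertex noise (~3% of shape variance),
which the end-to-end refinement experiments keep but the linear-algebra
validation deliberately excludes. These are properties — and limitations —
of the correspondence operator itself, documented rather than hidden.

## Preprocessing

Bias correction models the image as `v = u * f + n` with a smooth
multiplicative field `f`. The estimator works in the log domain: a total
degree-3 tensor polynomial is fitted to `log v` inside a cleaned foreground
mask (Otsu threshold, largest component, one-voxel erosion) by iteratively
reweighted least squares (Huber weights, default 4 iterations), and the
exponentiated, geometric-mean-normalised field is divided out. On phantoms
with known polynomial fields in [0.8, 1.2] this removes well over half of
the intensity non-uniformity inside the gland; on field-free phantoms it is
identity to within a fraction of a percent.

Intensity standardisation is landmark-based: percentile landmarks {1, 10,
25, 50, 75, 90, 99} of the foreground histogram are affinely anchored to
[0, 4095], averaged across the training set, and new volumes are mapped by
the continuous monotone piecewise-linear transform that sends their own
landmarks exactly onto the standard positions, with terminal segments
extended linearly. Two deliberate choices: the foreground is rank-defined
(voxels strictly above the volume median) because rank selection is
invariant under monotone maps — this is precisely what makes
standardisation idempotent to sub-unit precision; and the histogram-mode
landmark is off by default (`include_mode = TRUE` enables it) because on
unimodal foregrounds the mode nearly coincides with the median and breaks
the strictly-increasing landmark invariant.

## Post-processing

Refined vertices become a mask in three steps: alpha-shape triangulation at
`alpha = 30` mm (the radius doubles automatically, up to the convex-hull
limit, if the sparse vertex cloud does not close at the nominal value —
near-cospherical vertex sets routinely produce tetrahedra whose
circumradius exceeds the local curvature radius); per-slice contouring by
in-plane rays from the mesh centroid at 11.25° steps (32 rays, a finer fan
than the correspondence stage to bound polygon discretisation error),
keeping the farthest intersection per ray; and even-odd scanline
rasterisation followed by 2D-then-3D hole filling, a 3D morphological
closing with a spherical element of radius 4 isotropic voxels (2 mm,
applied before downsampling), and nearest-neighbour resampling onto the
native grid.

## Numerical choices

* **Delaunay/alpha machinery.** The 3D Bowyer–Watson tetrahedralisation
  applies a deterministic jitter (10^-7 of the cloud diagonal) to break the
  cospherical degeneracies of voxel-grid clouds, and coincident input
  points (distinct rays can hit the same surface point) are collapsed
  before insertion; both are orders of magnitude below voxel size.
  Alpha-complex membership is circumradius <= alpha; boundary faces are
  those incident to exactly one kept tetrahedron, oriented outward.
* **Interpolation.** Intensities use Catmull–Rom cubic interpolation
  (exact on linear fields, which the profile tests exploit); masks use
  nearest neighbour, which provably preserves {0, 1}. Out-of-extent
  samples clamp to the edge value.
* **Distances.** Surface distances use an exact separable Euclidean
  distance transform honouring anisotropic spacing; HD95 takes the
  symmetrised maximum of the two directed 95th percentiles (directed
  variants are exposed, since the source's wording admits both readings).
* **Tie-breaks.** Equal-cost search positions resolve toward the smallest
  |movement| (damped evolution); multiple ray hits resolve to the largest
  ray parameter.
* **Degenerate inputs.** Constant volumes, empty masks, coplanar point
  sets, single-voxel masks and zero-length rays all raise early, specific
  errors rather than propagating NaNs.

## Problem sizes

The shipped experiments use desk-scale sizes chosen to exercise every code
path with comfortable statistical margins: 10-phantom training cohorts for
the refinement studies, 10 test cases x 4 ablation presets at corruption
severity 0.3, 30-shape cohorts x 5 seeds for mode recovery, 10,000 random
ray-triangle pairs and 20 random mask pairs for the geometry and metric
oracles.

## Known limitations

* The fixed-fan ray correspondence responds nonlinearly to large or
  moment-coupled deformations (quadratic vertex response once source
  points move with the shape); recovered PCA modes are then mixtures. This
  bounds the deformation regime in which mode recovery is meaningful.
* Vertices inside concavities bridged by the alpha shape sit on the bridge,
  not the true surface; detached blobs beyond the gland capture
  farthest-hit rays, which is why the pipeline cleans initial masks
  (largest component, hole fill) before extraction.
* The training loop for the initial-segmentation network is out of scope;
  the architecture is specified declaratively (and verified by its exact
  trainable-parameter count, 1,192,593 for the reference configuration),
  and initialisations come from any mask source through the pluggable
  initializer interface.
* Polar caps above ±67.5° elevation carry no corresponded vertices; the
  closing step compensates partially, and the round-trip Dice of the whole
  geometry stack on smooth phantoms stays ≥ 0.90.
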