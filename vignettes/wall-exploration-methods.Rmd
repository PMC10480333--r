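---
title: "Methods: multimodal exploration of the aneurysm wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal exploration of the aneurysm wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`iawall` combines four data sources around a resected intracranial
aneurysm dome — preoperative lumen surface model, ex vivo micro-CT,
multi-stain histology, and simulated hemodynamics — none of which can be
registered to the others by classical intensity- or landmark-based
methods. This vignette documents the models and the numerical choices, in
the order the pipeline applies them.

## Inner/outer labelling of wall meshes

The resected dome is a bowl: one side of the wall faced the blood (the
lumen side), the other faced the brain. Given a watertight triangle mesh
of the wall, the package labels a vertex *inner* when the open segment
between the vertex and the mesh center (the arithmetic mean of all
vertices) contains no point interior to the wall. Assumptions: the mesh
encloses the wall *material* (so "interior" means inside the tissue, not
inside the cavity), and the center falls into the cavity of the bowl —
true for bowl-like shapes, while for a solid convex body the center is
interior and every vertex is correctly labelled outer.

Numerical choices:

* The interior test is a segment–triangle intersection (Möller–Trumbore)
  with the segment shrunk by a fraction `eps = 1e-6` at the vertex end,
  because a literal test always terminates *on* the surface and would
  trivially hit the vertex's own incident faces.
* A mesh whose enclosed volume is numerically zero (a degenerate
  zero-thickness shell) has an empty interior; every vertex is then inner
  by definition of the rule.
* Non-watertight input is a hard error carrying the offending boundary
  edges, since "interior" is undefined for open surfaces.
* The majority-vote refinement updates vertices sequentially in index
  order and repeats to a fixed point (cap 100 passes); ties and isolated
  vertices keep their label. Sequential updating makes the result
  deterministic; a single-pass mode exists for the literal one-sweep
  reading.

Wall thickness is estimated per vertex as the distance to the nearest
vertex of the opposite class — a resolution-limited proxy that needs both
classes present.

## Virtual inflation

The dome collapses after resection. Inflation restores it using the
preoperative lumen surface as the ground truth for how far to inflate:
per iteration each inner vertex moves `step_fraction` of the way toward
the centroid of its `k_target` nearest target vertices, and each outer
vertex moves by the mean displacement of its `k_inner` nearest inner
vertices, which preserves the local wall thickness by construction.

Parameters (defaults): `k_target = k_inner = 5` — the attraction is
plural-neighbour but local; larger values oversmooth the restored shape.
`step_fraction = 0.5` damps the otherwise oscillatory jump onto the
discrete target vertex set. `max_iterations = 200`,
`convergence_tol = 1e-3` mm: iteration stops when the largest inner move
falls below the tolerance, which is far below the mesh resolutions in
use. Outer vertices move in every iteration (not once at the end) so all
intermediate meshes remain valid shells. The method is purely geometric:
no elastic model, no self-intersection handling, and nearest neighbours
are target *vertices*, not closest points on triangles.

Two consequences are worth stating. First, the fixed point of the inner
update is the centroid of the nearest target vertices, so the restored
inner surface lies marginally inside the target sphere by a
discretization-dependent amount. Second, since the outer surface rides on
the inner displacements, the post-inflation shell volume is approximately
(covered lumen area) × (wall thickness); inflation is volume-neutral
exactly when the collapse was near-isometric, which is the physically
expected regime (thin tissue bends much more cheaply than it stretches).

## Histology processing

Stain classification uses a single-hidden-layer neural network
(`nnet`, 8 hidden units, weight decay 1e-3) on 30 colour features
(8-bin histogram + mean + sd per RGB channel). The contract is the 4-way
label HE/MT/ORO/ASMA, not any particular architecture; colour histograms
carry essentially all of the stain signal, and the model trains in
seconds on dozens of patches.

Segmentation assumes the scanned slide has three luminance populations:
near-black scanner padding, stained tissue, and light slide background.
Both thresholds are found at once by three-class (two-threshold) Otsu on
Rec. 601 luminance; the tissue is the middle class. All four stains use
this same path — H&E and MT are simply darker than ORO and aSMA, which
the per-image thresholds absorb. Connected components smaller than
`min_object_area` (default 0.1 % of the image) are removed as dissected
fragments or impurities, interior holes (nuclei, lipid droplets darker
than the padding threshold) are filled, and the boundary is refined by a
morphological geodesic active contour: the edge-stopping function
`g = 1 / (1 + 200 |∇(G_2 * I)|²)`, an advection step moving the front
along `∇g`, and a 3×3 binary majority filter as the curvature term
(`gac_iterations = 100`). Images larger than 4096 px on a side are
processed on a downsampled proxy and the mask is upsampled back.

## Contour split, sectioning and 2D mapping

The 2D analogue of the mesh labelling splits a closed tissue contour into
inner (concave, lumen-facing) and outer points: the contour center is the
mean of the contour points, and a point is inner when the center–point
segment meets no other boundary edge. Edges whose endpoints lie within
`excl_radius = 2` px of the tested point are its own boundary
neighbourhood and are excluded; the u-shape makes it legitimate for the
center to lie outside the polygon.

Sectioning resamples the inner chain uniformly by arc length to
`n_sections = 5000` positions; each is paired with the window of
`outer_per_section = 50` consecutive outer points centred at the matching
relative arc-length position of the outer chain, traversed in the
opposite contour direction so both chains run from one u-tip to the
other. Consecutive windows overlap; sections 1 and n sit at the tips,
where the inner-to-outer distance is minimal.

Mapping transfers pixel values along matched outer→inner segments by
arc-length reparameterization. The ratio ‖b‖/‖a‖ acts on the *coordinate*
(`g(x) = f(x·‖a‖/‖b‖)`), not on the value: value scaling would corrupt
colours, and both readings coincide in the self-mapping case. Sampling
marches at half-pixel steps along the longer segment; for each visited
target pixel the pixel center is projected onto the target segment and
the source is read by bilinear interpolation at the corresponding
relative position, which makes self-mapping nearly exact. A pixel accepts
at most `update_cap = 5` contributions (overlap-induced blurring is
bounded) and stores their average. Mask pixels missed by every segment
are optionally filled from the nearest mapped pixel. Fidelity is
quantified as the Pearson correlation of luminance over the mask; it
rises with image resolution, because a 50-point outer window spans a
smaller fraction of the tissue.

The dilation-robustness experiment dilates the target mask with disks of
increasing radius to mimic growing shape mismatch between histology and
micro-CT; correlations against the original image decrease monotonically
with radius. The absolute values depend on the image's spatial frequency
content: high-frequency texture decorrelates after a displacement
comparable to its feature size, so small phantoms degrade faster than
large clinical slides.

## Slide-stack alignment

A slide stack is an ordered table of stains (or placeholders for removed
sections) and thicknesses in µm. Positions use the mid-slice convention
(cumulative thickness of the preceding slides plus half the slide's own),
the stack length is the thickness sum including placeholders, and the
length report compares it to the expected sample length, estimating
missing slides as discrepancy / median thickness. A stack longer than the
sample is flagged rather than treated as an error: fixation shrinks
tissue. Cross-section masks for any cutting plane come from ray-parity
rasterization of the watertight mesh at a configurable px/mm.

## Rigid field transfer

Point-to-point ICP registers the dome to the micro-CT surface:
closest-vertex correspondences, closed-form Kabsch update, repeated until
the RMS improvement falls below `tol = 1e-6` mm. ICP is local, so
initialization aligns centroids and optionally the principal axes, trying
the four sign-consistent axis orientations and keeping the lowest-RMS
one; divergence (final RMS above initial) yields a warning and the best
transform seen. Transform recovery is only well-posed for asymmetric
shapes — for a surface of revolution any azimuthal rotation is a
symmetry, and ICP will return a symmetry-equivalent pose with equally
zero residual. The recovered transform is propagated to the preoperative
model, and each voxel center of the target grid receives the field value
of its nearest model vertex (ties to the lowest index, no interpolation),
so the voxel volume's range never exceeds the field's.

## Synthetic phantoms

The generators emulate the study's data at desk scale, with ground truth:

* **Dome**: a hemispherical shell (outer radius 5 mm, wall 0.5 mm —
  aneurysm-scale dimensions) closed by a rim band. Deflation is an inward
  radial buckling dimple, deepest at the pole (depth
  `0.45 · deflation_factor` of the radius) and vanishing at the rim. The
  dimple width is solved at construction so the inner surface keeps the
  area of the undeformed lumen hemisphere: collapse of a thin wall is
  bending-dominated and therefore near-isometric. The outer surface is
  the constant-distance normal offset, so ground-truth thickness is exact.
  The lumen target is an icosphere of the inner radius.
* **Histology**: a u-shaped band (annulus with an angular opening) on a
  light slide background inside a dark padding frame, with per-stain
  base/accent palettes chosen to mimic each stain's look while remaining
  linearly separable in colour space, seeded accent blobs as texture, and
  mild (sd 0.01) pixel noise.
* **WSS**: a positive axial gradient or Gaussian spot per vertex —
  consumed, never computed; CFD is out of scope.
* **Micro-CT**: per-plane cross-section masks of the dome plus spherical
  calcification deposits clipped to the wall. The emulated acquisition is
  10 µm isotropic; the default 20 px/mm keeps tests fast.

What the phantoms do **not** model: staining variability and artefacts
(folds, tears), non-revolution dome geometries, anisotropic collapse,
partial-volume effects in micro-CT, or realistic WSS spatial structure.
Passing tests therefore demonstrate the geometric correctness and
self-consistency of the pipeline, not clinical-grade robustness.

## Problem sizes and reproducibility

Test and acceptance runs use a ~2000 px histology phantom for the
full-scale self-mapping check, 300–1200 px phantoms elsewhere, dome
meshes of 24–48 azimuthal segments (about 1000–2300 vertices), and a 20³
voxel grid for the exhaustive nearest-neighbour cross-check; brute-force
oracles (segment sampling against a ray-parity inside test, all-edges
polygon intersection, exhaustive voxel search) are implemented
independently in plain R in the test helpers. All generators are
deterministic under a fixed seed, and the pipeline bundle embeds its
resolved configuration so a rerun reproduces byte-identical outputs.

## Known limitations

* The inner/outer rule assumes a star-shaped-enough cavity; exotic
  folded domes can occlude genuinely lumen-facing vertices.
* Inflation has no collision or elasticity model; heavily creased
  collapses can map many inner vertices onto the same target region.
* The contour machinery assumes one simply connected u-shaped component
  per slice; multi-fragment slides are reduced to their largest
  component with a warning.
* Correlation is computed on luminance only; hue shifts that preserve
  luminance are invisible to it.
* ICP provides rigid alignment only — the deformable residual between ex
  vivo and in vivo shapes is handled upstream by virtual inflation, not
  by the registration.
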