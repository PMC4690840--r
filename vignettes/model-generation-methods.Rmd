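---
title: "From tagged segmentation to fiber-annotated tetrahedral model: methods"
author: "cardiomesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tagged segmentation to fiber-annotated tetrahedral model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomesh)
```

## The problem

Organ-scale cardiac electromechanics needs tetrahedral meshes at a much
finer resolution (~100 µm) than the clinical segmentations they start from
(~1–1.5 mm). Meshing a coarse label image directly imprints voxel
"staircase" artifacts on every anatomical surface. `cardiomesh` implements
the standard remedy as a fully automatic workflow: extract the tagged
boundary surfaces of the segmentation, smooth them under a strict
half-voxel displacement guarantee, re-rasterize the smoothed surfaces at
modeling resolution, mesh the upsampled image into tag-carrying tetrahedra,
derive the anatomical boundary surfaces by face-set algebra, and assign
myocardial fiber orientations with a Laplace–Dirichlet rule-based method.
Everything downstream of the segmentation is deterministic and scriptable;
`run_pipeline()` composes the stages and writes CARP/VTU artifacts plus a
manifest.

## Surface extraction

Each tag's binary indicator is sampled at voxel centers, padded with
background, and contoured at isovalue 0.5. We use the tetrahedral
decomposition variant of marching cubes (each lattice cell is split into the
six Kuhn tetrahedra; each tetrahedron contributes 0–2 triangles depending on
its binary corner pattern). Two properties motivated this choice over the
classic 256-case cube table:

* there are no ambiguous configurations, so the surface is always closed
  and consistently orientable; and
* vertex positions are *midpoints of lattice edges*, which makes the
  triangulations extracted from two abutting tags coincide exactly over the
  interior of their shared interface. The quad split inside a tetrahedron
  uses the diagonal anchored at the lowest-numbered cut edge, a rule that is
  invariant under swapping inside and outside, so both tags produce the same
  two triangles.

`merge_tag_surfaces()` deduplicates vertices (tolerance 1e-6 mm; vertices of
lattice surfaces are exactly equal) and collapses coincident face pairs into
single faces labelled with the ordered tag pair `(inner, outer)`, removing
the duplicated interface. Near three-material junction lines, per-tag
contours of a binary mask are not reducible to a single shared sheet
(tetrahedra there contain corners of three materials); those faces remain
per-tag. This is harmless downstream: rasterization classifies voxels
against each tag's *closed* surface independently, and smoothing acts on the
merged vertex set, so junctions stay consistent to within the half-voxel
bound. A `blocky` extraction mode emits the exact voxel-face surface (volume
exactly voxel count × voxel volume), used for exact-arithmetic round-trip
tests and as the inverse of rasterization at source resolution.

## Constrained variational smoothing

Smoothing minimizes the quadratic norm of the discrete Laplacian of the
vertex positions,

$$\min_X \|L X\|_F^2 \quad \text{s.t.} \quad |X_{ia} - X^0_{ia}| \le
\tfrac{1}{2} h_a ,$$

where $X^0$ are the extracted positions and $h_a$ the source voxel size per
axis. The box half-width of 0.5 voxel guarantees the smoothed surface stays
within the margin of error of the segmentation; it is exposed as
`box_halfwidth_voxels` (a Euclidean-ball variant of the same radius is
available for sensitivity checks, and per-axis half-widths generalize the
bound to anisotropic voxels). The default $L$ is the uniform "umbrella"
graph Laplacian, row $i$ encoding $x_i - \mathrm{mean}(\text{neighbors})$;
cotangent weights are optional. The objective separates per coordinate axis
and is convex, so the solver choice only affects the path, not the optimum:

* default: monotone accelerated projected gradient (FISTA update with a
  fallback to the plain projected-gradient step whenever the accelerated
  candidate would increase the objective), step size $1/(2\|L\|_2^2)$ from a
  power-iteration estimate, projection onto the box after every step so
  feasibility is exact at all times;
* alternative: ADMM with a cached sparse Cholesky factor of
  $2L^\top L + \rho I$.

Both are verified against a dense box-constrained QP solved independently by
`optim(method = "L-BFGS-B")` on toy surfaces. Iterations stop when the
relative objective decrease falls below `tolerance` (default 1e-8);
non-convergence returns the best iterate with a warning flag in the report.
Because adjacent extracted vertices can be only half a voxel apart, the
optimum may collapse a few vertices; the resulting zero-area faces are
parity-neutral and are tolerated everywhere downstream (they are rejected
only where a strict manifold is asserted).

## Rasterization

`rasterize_surfaces()` classifies every target voxel center against each
tag's closed surface by parity of ray crossings along +x. The ray origin is
offset by a fixed sub-voxel fraction of the spacing in y and z, so rays
cannot hit triangle edges or vertices of lattice-aligned surfaces; the
classification is deterministic, with no randomness. Voxels inside exactly
one tag take that tag; voxels inside none are background; the rare voxels
inside several tags (possible only through numerical overlap of smoothed
surfaces) go to the tag with the nearest surface, ties to the lowest label.
Output bounds default to the source image bounds padded by one target voxel.
Extract-then-rasterize at the source spacing in blocky mode is the exact
identity on labels, which pins down all grid conventions (voxel centers at
`origin + (i + 0.5) * spacing`).

## Meshing

The upsampled image is already at modeling resolution, so each foreground
voxel is split into six positively oriented Kuhn tetrahedra on the shared
corner lattice; the Kuhn (Freudenthal) split is translation-invariant and
therefore conforms across voxel faces without any parity bookkeeping.
Element tags are inherited from voxel labels, so per-tag element volumes
equal voxel count × voxel volume exactly and region boundaries are
watertight. An optional constrained boundary relaxation (umbrella smoothing
of boundary nodes, capped at ±0.5 voxel, with inverted-element moves
reverted) is available but off by default. True boundary-fitted, locally
refined meshing is out of scope; externally generated meshes can be imported
through the CARP text reader and used for surface tagging and fibers
unchanged.

## Boundary surfaces by face-set algebra

`tag_boundary()` returns the topological boundary of an element tag set
(faces incident to exactly one selected tetrahedron); the background region
is representable as the complement (the global mesh boundary). Canonicalized
face triples support exact union/intersection/difference. From these,
`derive_bc_surfaces()` builds the inputs the fiber rule needs:

* endocardia as pool–myocardium interfaces. On the septum the RV blood pool
  abuts *LV* myocardium, so "RV endocardium" is defined as
  ∂(RV pool) ∩ ∂(myocardium), not merely the RV-myocardium faces — the
  Dirichlet sets must cover the full cavity surface;
* per-ventricle epicardium as the *intersection* of the ventricle boundary
  with the background boundary, and total epicardium as the *union* of the
  two — the semantically consistent reading of the standard set formulas
  (formulations in the literature sometimes swap the words and the symbols);
* base as myocardium–base-tag interface (or, absent a base tag, the
  myocardial boundary faces on the maximal-z plane);
* apex as the extremal epicardial node along −z (ties broken by node index).

These four sets are pairwise disjoint and together cover the myocardial
boundary exactly; both facts are asserted in the tests.

## Laplace–Dirichlet fiber assignment

Four harmonic fields are solved on the myocardial submesh with linear
tetrahedral finite elements: `phi_epi` (epicardium 1, both endocardia 0),
`phi_lv` (LV endocardium 1, RV endocardium and epicardium 0), `phi_rv`
(symmetric), and the apicobasal `psi` (apex 0, base 1). The apex condition
is imposed on a small epicardial patch around the extremal node (5% of the
long-axis extent): a single-point Dirichlet condition has vanishing capacity
in 3D, which would leave `psi` nearly constant with a noise-dominated
gradient. The solver is Jacobi-preconditioned conjugate gradients to a
relative residual of 1e-10; the discrete maximum principle is checked on
every solve (lattice meshes give well-behaved stiffness matrices; a
violation on an imported mesh raises a warning rather than silent
acceptance).

Gradients are evaluated per element (constant on linear tetrahedra; frames
are never built from nodally averaged fields, so the LV/RV junction does not
smear). Two robustness steps precede frame construction: elements whose four
nodes all lie on one Dirichlet surface — where any harmonic field is
constant and the element gradient exactly zero — take the mean gradient of
their face neighbors, and a small number of neighbor-averaging passes
(`gradient_smoothing`, default 2) damps the 90-degree staircase jitter that
a voxel-lattice boundary imprints on the surface element layer. The fields
themselves are smooth, so interior directions are essentially unchanged.
Then, per element:

1. an LV frame is built from $\nabla\psi$ and the transmural candidate
   $\nabla(\phi_{epi}-\phi_{lv})$ — the harmonic contrast with boundary
   values +1 on the epicardium and −1 on the LV endocardium, which unlike
   $-\nabla\phi_{lv}$ alone stays non-degenerate in the apical plug below
   the cavity and in the opposite free wall: apicobasal axis
   $\hat e_\ell = \nabla\psi/\|\nabla\psi\|$, transmural axis
   $\hat e_t$ = the candidate orthonormalized against $\hat e_\ell$,
   circumferential axis $\hat e_c = \hat e_\ell \times \hat e_t$ (the RV
   frame uses $\nabla(\phi_{epi}-\phi_{rv})$);
2. each frame is rotated about its transmural axis by the helix angle
   $\alpha(d) = \alpha_{endo}(1-d) + \alpha_{epi}\,d$ with $d = \phi_{epi}$
   the transmural depth, and the sheet axes about the fiber by $\beta(d)$;
3. LV and RV frames are blended by quaternion spherical-linear interpolation
   with sign disambiguation (a simplified bislerp; a per-axis linear blend
   with re-orthonormalization is available as `interpolation =
   "linear-frame"`), weighted by the relative transmural position
   $w = \phi_{rv}/(\phi_{lv}+\phi_{rv})$, which is 0 in the LV free wall, 1
   in the RV free wall, and sweeps across the septum.

Since $d = \phi_{epi} \approx 0$ throughout the septum (both septal surfaces
are endocardial), septal fibers stay near $\alpha_{endo}$; this is the
standard behavior of this field choice and is documented rather than
patched. Elements with a degenerate apicobasal gradient (e.g. at the apex
singularity) fall back to a deterministic world-axis completion. The default
angles ±60°/0° are the conventional values for this family of rules; they
are configuration, not constants — tests exercise the rule symbolically
through the configured values.

Verification uses idealized geometries with closed-form harmonic
coordinates: a boundary-fitted cylindrical annulus (`annulus_mesh()`), where
the transmural coordinate is $\ln(r/r_1)/\ln(r_2/r_1)$ and the recovered
helix angle must follow the configured linear law (slope within 10%,
R² > 0.95, mid-wall angle within 2° for symmetric settings), and a
voxelized spherical shell for the solver itself (exact-trace Dirichlet data
isolates discretization error; observed L2 convergence order ≈ 1.7–2).

## The synthetic phantom

The paper-scale input is a clinical tagged segmentation; tests and the
acceptance run use a synthetic stand-in with analytically known surfaces: a
truncated ellipsoidal LV shell fused with an offset RV shell (the overlap is
relabelled LV, making the septum LV tissue and the RV a crescent), blood
pools, a flat base cut at a fixed fraction of the long axis with a one-voxel
base cap carrying the base tag, and the apex at the −z pole. Defaults —
LV outer semi-axes (16, 16, 26) mm with a 5 mm wall, RV outer
(14, 17, 22) mm offset (−12, 0, 3) mm with a 3.5 mm wall, 80% of the long
axis retained, 1 mm isotropic spacing — are a compact idealized geometry
chosen once for a clinically realistic wall-thickness-to-voxel ratio while
keeping the full pipeline (including the 0.5 mm re-rasterized mesh of
~1.7 M tetrahedra) comfortably desk-scale. Every analytic surface ships
with an exact signed-distance evaluator (point-to-ellipsoid distance by
bisection on the Lagrange parameter), so smoothing accuracy is measured
against ground truth rather than against another discretization.

Segmentation noise is emulated by `add_boundary_noise()`: every voxel
6-adjacent to a differing label is, with probability p, reassigned the label
of a uniformly chosen differing neighbor, all reassignments computed
simultaneously from the input labels and driven by a single explicit seed —
the only source of randomness in the package. What the phantom does *not*
emulate: trabeculation and papillary muscles, valve annuli, atria and
vessels, intensity-dependent segmentation bias, and anisotropic slice
profiles. Passing tests therefore demonstrate the pipeline's geometric and
numerical contracts, not robustness to every clinical segmentation
pathology.

## Numerical choices and edge cases

* Grids are axis-aligned only; oblique NIfTI orientations are rejected
  rather than silently resampled, keeping the voxel↔world map exact.
  Labels are unsigned integers ≤ 65535, 0 reserved for background.
* Shells thinner than half a voxel are refused at phantom generation
  ("shell not resolvable").
* Closedness of a surface is the parity-defining property (every directed
  edge balanced by its reverse); strict 2-manifoldness is a separate,
  optional assertion — blocky surfaces of masks with edge-contact
  configurations are closed but legitimately non-manifold.
* The multi-tag conflict rule in rasterization (nearest surface, ties to
  lowest label) and the ray-offset constants are fixed design choices, so
  identical inputs give byte-identical outputs; the end-to-end determinism
  of the CARP artifacts is itself a test.
* CG tolerance 1e-10 (relative residual), smoothing tolerance 1e-8
  (relative objective decrease), vertex merge tolerance 1e-6 mm, degenerate
  face threshold 1e-12 mm²: all small relative to the half-voxel geometric
  scale the pipeline guarantees.

## Problem sizes used in the shipped checks

Unit tests run the phantom mostly at 2 mm spacing; the smoothing-bound and
staircase checks use the 1 mm phantom; the solver-convergence pair uses the
spherical shell at 1 and 0.5 mm; the fiber checks use the structured annulus
(≈ 21 k elements); and the determinism check runs the full pipeline twice at
the default 0.5 mm target (≈ 1.7 M tetrahedra, ≈ 305 k nodes per run). These
sizes are the package's chosen verification conditions; all thresholds are
stated above, none are fitted to outcomes.

## Known limitations

* No boundary-fitted or locally refined meshing; element counts of
  commercial octree meshers are not reproducible with the lattice split.
* Atria, valve structure, atlas-based and DT-MRI fiber mapping are out of
  scope; the fiber rule covers the two ventricular walls and septum.
* Per-tag marching surfaces near three-material junction lines keep
  per-tag sheets (see above); applications needing a single non-manifold
  junction complex should post-process the merged surface.
* The septal transmural coordinate of this field choice compresses toward
  the endocardial angle, as noted.
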