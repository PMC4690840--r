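# cardiomesh

Automatic construction of tagged, fiber-annotated tetrahedral models of
biventricular cardiac anatomy from segmented 3D label images — the
model-generation half of an organ-scale cardiac electromechanics workflow,
for researchers who have an anatomically tagged segmentation (LV/RV
myocardium, blood pools, base) and need a simulation-ready mesh.

Clinical segmentations live at ~1–1.5 mm; electromechanics meshes need
~0.1–0.5 mm. Meshing the coarse label image directly imprints voxel
staircase artifacts on every surface. `cardiomesh` implements the standard
pipeline instead:

1. **Surface extraction** — per-tag marching cubes (tetrahedral variant) at
   isovalue 0.5 on the binary indicator of each tag; coincident interface
   triangles merged into faces labelled `(tag_inner, tag_outer)`.
2. **Constrained variational smoothing** — minimize the quadratic norm of
   the surface Laplacian, ‖L X‖², subject to per-vertex box constraints
   |X − X⁰| ≤ 0.5 · voxel, so the smoothed surface provably stays within
   the segmentation's margin of error.
3. **Re-rasterization** — render the smoothed tagged surfaces into a new
   label image at arbitrary (typically much finer) resolution by
   deterministic ray-parity point classification.
4. **Meshing** — split each foreground voxel of the upsampled image into 6
   conforming Kuhn tetrahedra carrying the region tag.
5. **Surface tagging** — derive LV/RV endocardium, epicardium, base and
   apex by exact set algebra on canonical boundary-face sets
   (Γ_epi = (Γ_LV ∩ Γ_B) ∪ (Γ_RV ∩ Γ_B), endocardia as pool–myocardium
   interfaces).
6. **Fibers** — Laplace–Dirichlet rule-based orthotropic triads: harmonic
   fields φ_epi, φ_lv, φ_rv, ψ (P1 finite elements, CG to 1e-10), local
   (circumferential, apicobasal, transmural) frames from their gradients,
   helix angle α(d) = α_endo(1−d) + α_epi·d across the wall (defaults
   ±60°), LV/RV frames blended by quaternion slerp.

Synthetic biventricular phantoms (truncated ellipsoidal shells with exact
signed-distance evaluators and seeded boundary noise) stand in for clinical
segmentations in all tests. Formats: NIfTI/NRRD label images (+ JSON tag
sidecar), STL/VTK surfaces, VTU meshes, CARP `.pts/.elem/.lon/.surf`.

## Worked example

```r
library(cardiomesh)

cfg <- pipeline_config(
  input = phantom_spec(spacing = 1, noise_probability = 0.2, seed = 42),
  target_spacing = 0.5,
  output_dir = "model_out", seed = 42)
bundle <- run_pipeline(cfg)
#> [input] done in 0.1 s
#> [extract-surfaces] done in 1.1 s
#> [smooth] done in 7.8 s
#>   max displacement: 0.5000 voxels
#> [rasterize] done in 6.3 s
#> [mesh] done in 1.1 s
#>   304291 nodes, 1711020 tetrahedra
#> [tag-surfaces] done in 8.6 s
#> [fibers] done in 20.3 s
#> pipeline finished in 65.8 s

bundle$smoothing_report
#> smoothing_report: objective 3252.3 -> 170.854 in 443 iterations
#>   max displacement 0.5 voxels

print(bundle$mesh)
#> tet_mesh: 304291 nodes, 1711020 tetrahedra
#>   tag 1 LV_myo: 716664 elements
#>   tag 2 RV_myo: 268554 elements
#>   tag 3 LV_pool: 488382 elements
#>   tag 4 RV_pool: 196758 elements
#>   tag 5 base: 40662 elements
```

The smoothing report certifies the half-voxel guarantee: no vertex moved
more than 0.5 of the source voxel size from its marching-cubes position
(the objective drop is the staircase energy removed). The mesh keeps one
tag per element, so per-region volumes are exact voxel sums, and the
`model.pts/.elem/.lon` files in `model_out/` are ready for a CARP-style
simulator — `.lon` holds the per-element fiber and sheet unit vectors.
A transmural helix-angle summary of the fibers:

```r
sub <- submesh(bundle$mesh, c(1, 2))
helix_angle_profile(sub, bundle$fibers, attr(bundle$fibers, "fields")$phi_epi,
                    n_bins = 5)
#>   d_mid mean_helix_deg      n
#> 1   0.1     54.9002299 283609
#> 2   0.3     22.5382994 126058
#> 3   0.5     -0.2185951 139237
#> 4   0.7    -22.8256249 164798
#> 5   0.9    -27.4759913 271516
```

— the configured +60°/−60° endo-to-epi law: near-zero at mid-wall and a
monotone sweep across the bins. The profile's read-out rebuilds local axes
from the transmural field gradient and the global long axis, so the
epicardial bin, dominated by the lattice boundary element layer where that
frame tilts, under-reads the rule's −60° extreme; the quantitative
recovery test lives on the boundary-fitted idealized annulus (slope within
10%, R² > 0.95).

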