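---
title: "Measuring crista ampullaris orientation and solving gravity alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring crista ampullaris orientation and solving gravity alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestigeom)
```

## The problem

Benign paroxysmal positional vertigo (BPPV) is driven by the interaction of
displaced otoconia with the cupula of a semicircular canal, so both
diagnosis (Dix-Hallpike and related positioning tests) and repositioning
maneuvers are at bottom exercises in three-dimensional geometry: where,
exactly, is the sensory plane of each crista ampullaris, and through which
head rotation does it become parallel or perpendicular to gravity?

`vestigeom` implements that geometry as a tested pipeline. Starting from
segmented labyrinth surfaces (meshes or point sets), it

1. builds a standard (mean) inner-ear model from a population by iterative
   correspondence and Procrustes averaging;
2. anchors a standardized head coordinate frame on the mean model
   (X to the subject's right, Y forward, Z up) from the bilateral symmetry
   plane of the two labyrinths and the horizontal plane through the tops of
   the common crura and the bottoms of the eyeballs;
3. calibrates individual specimens rigidly into that frame, transferring
   the calibration exactly to sibling structures (membranous labyrinth,
   crista patches) segmented from the same scan;
4. fits total-least-squares planes to crista patches and canal centerlines
   and tabulates their angles to the sagittal, coronal and horizontal
   reference planes;
5. solves, in closed form, for head rotations that place a crista plane
   parallel or perpendicular to gravity — the "zero-point" orientations
   with minimal gravity-driven ampullary stimulation.

## Planes, angles and sign conventions

Each plane is stored in Hessian form $Ax + By + Cz + D = 0$ with unit
normal $(A, B, C)$. Plane fitting is total least squares: the normal is the
least-variance eigenvector of the centered scatter matrix and the centroid
lies on the plane. We deliberately avoid ordinary regression of $z$ on
$(x, y)$, which degenerates for the near-vertical crista planes, and avoid
summarizing the saddle-shaped crista by a line through its endpoints, which
discards most of the surface.

Angles to the reference planes are the arc-cosines of the normal's
direction cosines, reported in degrees on $[0, 180]$ and *not* folded to
the acute range: the sign of each normal carries anatomical meaning
(superior canal normal outward, posterior inward, lateral downward), and
folding would destroy the distinction between, say, an inward- and an
outward-facing crista. One consequence worth knowing: the angle between an
oriented crista normal and its own canal plane typically comes out obtuse
(≈99° for the posterior canal reference values); the acute dihedral angle
between the two planes is available via
`angle_between_planes(..., folded = TRUE)` and lies in the published
81–86° "nearly perpendicular" band.

A second numerical subtlety: published normals quoted to 4 decimals are
accepted by `reference_plane_angles()` exactly as printed, without
renormalization. Renormalizing a 4-decimal normal perturbs the angle at the
second decimal, which is visible when checking reproduced tables against
printed ones.

```{r angles}
att <- build_angle_tables(
  setNames(lapply(reference_normals()$label, function(l)
    plane(reference_normal(l))), reference_normals()$label))
head(att$attitude, 3)
```

## The mean model and the head frame

The averaging loop aligns all specimens to a running reference, averages
pointwise, and re-references on the average until the mean point
displacement falls below `tol` (default $10^{-3}$ mm, capped at 100
iterations). Re-referencing on the running mean is what removes the
dependence on the initial reference choice; the suite asserts invariance
under population reordering and reference choice. Population averaging
allows an isotropic scale (inner-ear size varies across subjects), with
the mean rescaled to the population's mean centroid size so sizes cannot
drift; specimen calibration into the finished frame is rigid-only, so
metric geometry (millimetres) is preserved for measurement.

Correspondence for unordered inputs is label-constrained
iterative-closest-point matching against the reference layout. For the
bundled synthetic data, correspondence is exact by construction (all
specimens are sampled on the same parameter grids), which keeps the test
pipeline sharp: ICP quality is tested separately from averaging quality.

The head frame resolves its chicken-and-egg problem ("top" and "bottom"
landmarks presuppose a vertical) the usual way: the symmetry plane is
estimated first and wins any conflict — the horizontal axis is
orthogonalized against it. The vertical sign is set by requiring the
eyeballs to be anterior (Y forward) of the common crura, and landmark
operationalization uses deterministic extreme vertices
(`pick_extreme_landmark()`, ties broken toward the lowest vertex index).

## Gravity-alignment solvers

For a rotation of angle $\theta$ about a fixed unit axis $a$, the rotated
normal dotted with gravity is $A\cos\theta + B\sin\theta + C$ with
$A = n \cdot g - (a \cdot n)(a \cdot g)$, $B = (a \times n) \cdot g$ and
$C = (a \cdot n)(a \cdot g)$, so parallel-to-gravity configurations
($n \perp g$) solve in closed form; perpendicular configurations about a
single axis are generically infeasible, and the solver then reports the
attainable extremum and points to the two-step maneuver (pitch about the
interaural axis nulling the normal's Y component, then roll about the
anteroposterior axis nulling X). Every returned solution is
back-substituted and must satisfy its condition to $10^{-9}$.

Clinical direction labels are bound to axis-sign pairs (right-hand rule):
positive rotation about X is "tilted back", negative "anterior pitch";
about Y, positive "tilt right"; about the craniocaudal Z axis in supine,
positive is "tilt left". With the published lateral-crista normal this
yields the familiar worked examples:

```{r solver}
lhc <- plane(reference_normal("LHC_CA"))
solve_single_axis(lhc, head_position("supine"), c(0, 0, 1), "parallel")[[1]]
solve_two_step_horizontal(plane(reference_normal("LPC_CA")))
```

Both zero-point conventions found in clinical discussion are exposed —
`"parallel"` (crista plane contains gravity; single-axis solve about the
clinically standard axis for the position) and `"perpendicular"` (crista
plane horizontal; two-step solve) — via
`zero_point_orientations(..., convention = )`; the package does not
declare either canonical.

## The synthetic generator

Because the underlying clinical image data are not redistributable, the
package ships a parametric phantom (`generate_specimen()`,
`generate_population()`): three mutually near-orthogonal canal circles per
side with torus ducts, ellipsoidal ampullae, saddle crista patches
$w = c\,(u^2 - v^2)$ with known true normals, a tapered common crus, and
eyeball spheres, bilaterally mirrored with exact left-right point
correspondence. Canal and crista normals default to the published
reference values — a fixture choice so that end-to-end runs reproduce the
published angle tables, not an anatomical claim. Other defaults are
plausible stylized scales chosen once: canal radii 2.9–3.2 mm, duct radius
0.45 mm, saddle coefficient 0.5 mm⁻¹ over a 1.5 × 1.0 mm patch sampled on
a 13 × 9 grid, eyeball radius 11 mm, and landmark placement with the
common-crus tops and eyeball bottoms coplanar in the canonical horizontal
plane. Population variability enters as per-canal rotation jitter
(Gaussian, degrees), isotropic size jitter (log-normal fraction) and
additive surface noise (mm); a bony-versus-membranous plane tilt of 1.5°
emulates the observed near-coplanarity of the two canal systems.

What the phantom does *not* emulate: real segmentation artifacts
(topological defects, partial volumes), true inter-subject shape modes
beyond rigid jitter and scale, and histologically realistic crista/cupula
morphology. Passing the recovery tests therefore demonstrates the
correctness of the geometry pipeline under its stated noise model, not
clinical-grade robustness on hospital data.

## Problem sizes and numerical choices

The test suite and the bundled pipeline run at desk scale, chosen as the
smallest sizes at which the statistical assertions are stable: populations
of 4–8 specimens (about 1,900 corresponded points each), Monte-Carlo
checks with 10–20 replicates, and a fixed seed per test. Convergence
tolerances are $10^{-3}$ mm for the mean model, $10^{-9}$ for solver
back-substitution, and $10^{-12}$ for frame orthonormality. Angles are
kept at full precision internally and rounded (2 decimals for tables, 1
for solver reports) only at serialization.

Known limitations: `establish_correspondence()` is plain ICP and needs a
rough pre-alignment for large pose offsets (the pipeline supplies centroid
initialization); the symmetry-plane estimator assumes roughly
mirror-comparable point sets; and the published own-canal and
membranous-versus-bony pairwise angles are matched only qualitatively
(near-perpendicular, near-parallel), since they do not reproduce exactly
from 4-decimal printed normals under any single sign convention.
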