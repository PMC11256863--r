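# vestigeom

Geometric analysis of the vestibular labyrinth for BPPV research: from
segmented inner-ear surfaces to the spatial orientation of each crista
ampullaris, and from there to the head rotations that align a crista plane
with gravity.

## What it computes

Benign paroxysmal positional vertigo (BPPV) therapy is applied geometry:
repositioning maneuvers work by steering the plane of the affected
semicircular canal's crista ampullaris relative to gravity. `vestigeom`
provides the measurement side of that reasoning:

- **Mean shape model.** A population of segmented labyrinths (point sets or
  meshes with point correspondence) is averaged by iterative Procrustes
  alignment, re-referencing on the running mean so the result does not
  depend on which specimen was chosen first.
- **Standardized head frame.** X points to the subject's right (normal of
  the bilateral symmetry plane of the two labyrinths), Z points up (normal
  of the horizontal plane through the tops of the common crura and the
  bottoms of the eyeballs, orthogonalized against X), Y = Z × X points
  forward.
- **Plane fitting.** Each crista patch and canal centerline gets a total
  least squares plane `Ax + By + Cz + D = 0`; the unit normal `(A, B, C)`
  is sign-oriented by anatomical convention (superior canal normal outward,
  posterior inward, lateral downward). Angles to the sagittal / coronal /
  horizontal reference planes are `acos` of the normal's direction cosines,
  in degrees on [0, 180], unfolded.
- **Gravity-alignment solvers.** For a rotation by θ about a unit axis *a*,
  `(R_a(θ)·n)·g = A cos θ + B sin θ + C` with
  `A = n·g − (a·n)(a·g)`, `B = (a×n)·g`, `C = (a·n)(a·g)`; the solver
  returns all closed-form roots with clinical direction labels, plus a
  two-step pitch-then-roll maneuver that makes any crista plane horizontal.
- **Synthetic phantom.** A parametric bilateral labyrinth generator with
  known ground-truth planes, landmarks and poses replaces the
  non-redistributable clinical scans and drives the end-to-end
  parameter-recovery tests.

## Worked example

Feeding the published left-ear crista normals to the angle tabulator and
the solvers:

```r
library(vestigeom)

planes <- setNames(lapply(reference_normals()$label, function(l)
  plane(reference_normal(l))), reference_normals()$label)
head(build_angle_tables(planes)$attitude, 3)
#>    label          A           B          C  sagittal  coronal horizontal
#> 1 LPC_CA -0.7469228 -0.10768887 -0.6561322 138.32452 96.18211   131.0056
#> 2 LHC_CA  0.9723049 -0.10520052 -0.2087010  13.51596 96.03872   102.0462
#> 3 LAC_CA  0.5364285 -0.08410446 -0.8397446  57.55916 94.82453   147.1132

lhc <- plane(reference_normal("LHC_CA"))
solve_single_axis(lhc, head_position("supine"), c(0, 0, 1), "parallel")[[1]]
#> Rotate 6.18 deg about (0, 0, 1): tilt left (residual 7.9e-15)

solve_two_step_horizontal(plane(reference_normal("LPC_CA")))
#> $pitch
#> Rotate 9.32 deg about (1, 0, 0): tilted back (residual 5.9e-17)
#> $roll
#> Rotate -48.32 deg about (0, 1, 0): tilt left (residual 0)
```

Reading: the left lateral crista plane (sagittal angle 13.5°, i.e. nearly
parasagittal) becomes parallel to gravity after a 6.2° leftward tilt in
the supine position; the left posterior crista plane becomes horizontal
after pitching 9.3° back and rolling 48.3° to the left. These are the
"zero-point" orientations of minimal gravity-driven ampullary stimulation.

The full simulate → average → calibrate → measure → solve pipeline runs as

```r
bundle <- run_pipeline(pipeline_config(n_population = 8, seed = 1,
                                       out_dir = "out"))
```

writing the attitude and pairwise angle tables (CSV), the mean model (PLY
plus JSON) and a residual/solution report (JSON). A thin CLI wrapper with
`simulate`, `run-all`, `angles` and `solve-orientation` subcommands lives
at `inst/cli/vestigeom.R`.

## Layout

- `R/geometry3d.R` — vectors, planes, TLS fitting, rotations, rigid
  transforms, sagittal mirroring
- `R/shape_model.R` — Procrustes alignment, ICP correspondence, iterative
  mean model
- `R/head_frame.R` — symmetry plane, head-frame construction, specimen
  calibration, landmark picking
- `R/crista_metrics.R` — crista/canal planes, cupula extrusion, angle
  tables
- `R/orientation_solver.R` — single-axis and two-step gravity alignment,
  zero-point orientations
- `R/synthetic.R` — phantom generator with ground truth
- `R/pipeline.R`, `R/mesh.R` — end-to-end pipeline, mesh and JSON/YAML I/O
- `vignettes/crista-orientation.Rmd` — methods and design notes
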