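Package: vestigeom
Title: Spatial Orientation of the Crista Ampullaris and Semicircular
    Canals from Labyrinth Surface Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Geometric analysis of the vestibular labyrinth for benign
    paroxysmal positional vertigo (BPPV) research. Builds a mean
    inner-ear shape model from a population of segmented labyrinth
    surfaces by iterative correspondence and Procrustes averaging,
    establishes a standardized head coordinate frame from bilateral
    symmetry and anatomical landmarks, fits total-least-squares planes
    to crista ampullaris patches and semicircular-canal centerlines,
    tabulates their angles to the sagittal, coronal and horizontal
    reference planes, and solves in closed form for head rotations that
    place a crista plane parallel or perpendicular to gravity
    (zero-point orientations). Includes a synthetic labyrinth generator
    with known ground truth for end-to-end validation, and ASCII
    PLY/OBJ/STL mesh input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
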