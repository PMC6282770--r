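Package: nurbstrack
Title: White-Matter Fiber Tractography by Rational B-Spline Curve Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Deterministic white-matter tractography that fits fiber pathways
    as nonuniform rational B-spline (NURBS) curves. Per-voxel diffusion
    directions are extracted from orientation distribution function (ODF)
    fields by mean-thresholded local-maxima detection, chained across
    26-connected voxels under distance, angle, length and anisotropy
    constraints, and fitted in two modes: tangent-consistent (control points
    from voxel-facet intersections plus voxel centers) and general (facet
    intersections only), with diffusion probabilities mapped to rational
    weights. Includes a multidirectional streamline baseline, local
    (spatial/tangent/curvature symmetric RMSE) and global (valid/invalid/no
    connection) tractogram evaluation metrics, synthetic phantoms with
    analytic ground truth, NIfTI-1 volume I/O and TCK/TRK tractogram I/O,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
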