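Package: tractfodf
Title: Voxel-Wise White-Matter Tract Segmentation from Full Spherical-Harmonic
    Fiber Orientation Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segments white-matter tracts voxel-wise from diffusion MRI fiber
    orientation distribution (fODF) fields represented as real even-order
    spherical-harmonic coefficient volumes (45 channels at maximum order 8),
    rather than from extracted peak vectors.  One binary 2D U-Net is trained
    per tract on axial, coronal, and sagittal slices; at inference the three
    per-view probability maps are averaged voxel-wise and thresholded at 0.5
    into a 3D mask.  Includes a seeded synthetic phantom generator producing
    crossing-fiber and bottleneck geometries with overlapping tract masks,
    a six-metric volumetric evaluation suite (Dice, volumetric overlap and
    overreach, specificity, precision, Jaccard), and a Wilcoxon/Bonferroni
    paired comparison harness, so the whole pipeline is testable without any
    external imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
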