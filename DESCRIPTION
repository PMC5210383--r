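Package: tdtract
Title: Tract-Density Tendon Segmentation and Muscle Fascicle Lengths from
    Diffusion-Tensor MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs skeletal-muscle fascicles from diffusion-tensor MRI
    with deterministic streamline tractography, segments tendinous tissue
    (tendon, aponeurosis, fascia) automatically as voxels whose normalized
    tract density exceeds a threshold, halts fascicle tracking there, and
    estimates per-muscle mean fascicle length from a skew-normal fit to the
    streamline length distribution. Includes a synthetic unipennate-muscle
    phantom with known ground-truth fascicle length, weighted linear
    least-squares tensor estimation, NIfTI/bvec/bval and TrackVis I/O, and
    test-retest repeatability statistics (Bland-Altman limits of agreement,
    coefficient of variation, minimal detectable difference).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
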