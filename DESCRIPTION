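Package: msdseg
Title: Mixed-Scale Dense Convolutional Networks for Bone Segmentation in
    CT Volumes Affected by Metal Artifacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-wise binary bone segmentation of cone-beam CT-like volumes
    corrupted by metal streak artifacts, using a mixed-scale dense (MS-D)
    convolutional network: densely connected 3x3 dilated convolutions with a
    cyclic dilation schedule, reflective boundaries and a two-class softmax
    output, trained with batch-size-1 Adam on axial slices. Includes a seeded
    synthetic phantom generator (parallel-beam radon transform, photon-count
    noise with beam hardening, filtered back-projection) that reproduces the
    bright/dark streak phenomenology of dental metal artifacts; Dice overlap
    evaluation with leave-2-out cross-validation; and a geometric evaluation
    chain from binary masks to triangle meshes (binary STL input/output) with
    signed surface-deviation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
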