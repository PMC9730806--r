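Package: lesioncascade
Title: Cascaded 3D Convolutional Detection of New Multiple Sclerosis
    Lesions in Longitudinal FLAIR MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects new multiple-sclerosis lesions between a baseline and
    a follow-up 3D T2-FLAIR scan with a cascade of two 3D patch-wise fully
    convolutional networks.  Each network couples a learned deformable
    registration U-Net (a spatial-transformer block trained with an
    image-similarity plus smoothness loss) with a two-branch segmentation
    U-Net, trained end-to-end; the second network is trained on the first
    network's mistakes to cut false positives.  Includes Nyul
    histogram-matching intensity standardization, lesion-centred and
    overlapped patch extraction with probability-map reconstruction,
    minimum-lesion-volume post-filtering, lesion-wise evaluation metrics
    (F1, PPVL, SensL, Dice, VolTested), and a two-timepoint phantom
    generator with known deformation and ground-truth lesions so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    oro.nifti,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
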