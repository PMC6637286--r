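Package: pulmovasc
Title: Quantitative Imaging and Molecular Pipelines for Neonatal Pulmonary
    Vascular Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the quantitative analysis chain used to phenotype
    experimental bronchopulmonary dysplasia with pulmonary hypertension
    (BPD-PH) in newborn mice: 3D micro-CT vessel-network extraction with
    diameter-binned counting and reference normalization, digital
    subtraction cine-angiography with branch-generation counting,
    precision-cut lung slice (PCLS) artery concentration-response analysis
    with four-parameter logistic fitting, Doppler-derived TPV/RVET and
    M-mode fractional shortening, and molecular quantification (delta-delta
    CT, total-protein normalization, positive-pixel scoring, Sirius Red
    collagen fraction, group statistics). Ships seeded phantom generators
    that emulate every input with ground truth attached, so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    car,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
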