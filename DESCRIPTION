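Package: natremri
Title: Sodium MRI and Diffusion Quantification for Preclinical Breast Tumour Imaging
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for preclinical sodium (23Na) MRI of
    orthotopic breast tumours: surface-coil B1 (1/r^2) intensity correction,
    region-of-interest statistics with phantom normalisation to tissue sodium
    concentration, apparent diffusion coefficient (ADC) mapping from
    diffusion-weighted series, linear discriminant classification of tumour vs
    non-tumour regions with leave-one-out cross-validation and ROC analysis,
    ex vivo ion calibrations (SBFI one-phase-association fluorescence and
    ion-selective microelectrode Pade(1,1) voltage curves), and a
    two-compartment tissue sodium model resolving extracellular and
    intracellular volume fractions. Ships a synthetic-data module that
    generates every input (Rician-noise magnitude images, diffusion series,
    cohort feature tables, fluorescence traces, electrode recordings) with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr
Config/testthat/edition: 3
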