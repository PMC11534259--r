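Package: na23tsc
Title: Tissue Sodium Concentration Mapping from Simulated 23Na MRI after
    Stereotactic Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative sodium (23Na)
    MRI of brain metastases treated with single-fraction stereotactic
    radiosurgery (SRS). Provides a longitudinal digital head phantom with
    tissue compartments at literature sodium concentrations, a simplified
    Gamma-Knife-like dose model prescribed to the 50% isodose, simulation and
    regridding reconstruction of density-adapted 3D radial sodium acquisitions,
    rigid co-registration and Gaussian-mixture tissue segmentation, tissue
    sodium concentration (TSC) quantification by vitreous-humor normalization
    with T1 correction, isodose-shell and healthy-ROI dosimetric statistics,
    and the longitudinal statistical analysis (paired t-tests with a
    normality check, dose-TSC Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    mclust,
    nortest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
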