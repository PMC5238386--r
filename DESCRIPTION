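Package: cilquant
Title: Peak-Pair Quantification and Biomarker Selection for Chemical
    Isotope Labeling LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for differential chemical isotope labeling (CIL)
    LC-MS metabolomics in which every metabolite appears as a
    co-eluting 12C/13C peak pair whose intensity ratio against a
    pooled heavy-labeled reference measures relative concentration.
    Provides a ground-truth simulator for dansylation-labeled
    studies, extracted-ion-chromatogram feature detection, peak-pair
    finding and chromatographic ratio quantification, cross-run
    alignment with zero-filling of missing ratios, tiered metabolite
    annotation, multivariate (PCA, OPLS-DA) and volcano statistics,
    and time-course biomarker selection for disease-progression and
    treatment studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mzR,
    mixOmics,
    optparse
Config/testthat/edition: 3
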