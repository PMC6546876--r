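Package: slpattern
Title: Searchlight Pattern Analysis of Gray-Matter Volume Maps
Version: 0.1.0
Authors@R:
    person("Searchlight", "Maintainers", email = "slpattern@example.org",
           role = c("aut", "cre"))
Description: Searchlight multivoxel pattern analysis (MVPA) for voxel-based
    morphometry: sphere geometry on volumetric grids, minimal NIfTI-1 input
    and output, leave-one-out cross-validated SVM-RBF classification of
    modulated gray-matter volume maps, exact binomial conversion of accuracy
    maps to p-value maps, 18-connected cluster extraction with label
    permutation testing, covariate-adjusted voxel-wise group comparison with
    Monte-Carlo cluster-extent correction, clinical group-comparison
    statistics, and a seeded synthetic cohort generator for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
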