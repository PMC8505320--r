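Package: indivBeta
Title: Individual-Based Temporal Beta-Diversity for Individual-Tracked Census Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pairwise and multiple-unit dissimilarity indices computed from
    individual-tracked census data (persistence, mortality and recruitment of
    marked individuals across an ordered census series), including
    individual-based analogues of the Sorensen and Bray-Curtis families
    (d_MR, v_s and their multiple-unit extensions via the inclusion-exclusion
    principle), exact-integer component decompositions, a brute-force
    inclusion-exclusion auditor, a randomization null model that preserves
    per-interval mortality and recruitment counts while randomizing which
    individuals die, the standardized effect size of individual persistence,
    and a neutral-drift census simulator for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), vegan, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'census.R'
    'io.R'
    'abundance.R'
    'pairwise.R'
    'multiunit.R'
    'oracle.R'
    'nullmodel.R'
    'simulate.R'
    'batch.R'
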