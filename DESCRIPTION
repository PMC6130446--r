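Package: connectokin
Title: Familiality and Heritability of Functional Connectomes via Connectotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits per-scan "connectotype" models of parcellated resting-state
    fMRI time courses, in which each region's signal is expressed as a weighted
    sum of all other regions, regularized by truncated singular value
    decomposition with the truncation rank chosen by cross-validation.
    Cross-prediction similarity between scan pairs is used to fingerprint
    individuals, to classify sibling versus unrelated pairs with
    Kolmogorov-Smirnov-ranked linear support vector machines under permutation
    nulls, and to partition similarity variance into heritable and
    shared-environment fractions via rank-transformed repeated-measures
    ANOVA sum-of-squares ratios. A synthetic cohort generator plants kinship
    structure in subject-level precision matrices so that every stage is
    testable without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
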