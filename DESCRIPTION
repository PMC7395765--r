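Package: fetallineage
Title: Somatic Mutation Accumulation and Developmental Lineages in Clonally
    Expanded Fetal Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for analysing somatic mutation accumulation in
    clonally expanded fetal stem and progenitor cells sequenced against a
    polyclonal bulk reference. Implements clone-versus-bulk somatic variant
    filtering (base substitutions and indels, including a beta-binomial
    clonality check), shared-variant calling across clones of a donor,
    developmental lineage-tree reconstruction from binary mutation matrices
    with branch-contribution estimation from bulk allele fractions,
    96-channel mutational spectrum construction with signature refitting
    (non-negative least squares, iterative reverse selection, bootstrap and
    fixed-margin permutation testing), and heteroscedastic linear
    mixed-effects models of mutation burden. A fully specified synthetic
    embryo/cohort generator provides seeded ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    MASS,
    ape,
    nlme,
    pracma,
    vcfR,
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
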