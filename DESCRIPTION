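Package: crctrace
Title: Case-Matched Spatio-Temporal Mutation Profiling of Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("crctrace", "maintainers", email = "crctrace@example.org",
           role = c("aut", "cre"))
Description: Tools for case-matched analysis of targeted panel sequencing of
    colorectal carcinomas and their liver and lung metastases across the
    disease course. Implements the standard molecular-pathology variant filter
    stack (allele-fraction cutoff with sub-threshold rescue, synonymous and
    common-polymorphism exclusion, named-variant blacklist), matched-normal
    germline subtraction, truncal versus lesion-private partitioning of
    somatic variants, synchronous versus metachronous metastasis
    classification, RAS hotspot status tracking through time, co-resected
    lesion concordance, cohort-level summary tables, and a seeded
    clonal-evolution cohort simulator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
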