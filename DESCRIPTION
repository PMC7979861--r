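Package: mesoevolve
Title: Multi-Region Tumour Evolution Analysis for Mesothelioma Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing tumour evolution from multi-region
    somatic variant calls and allele-specific copy-number segments:
    consensus variant filtering with force-calling, cancer-cell-fraction
    (CCF) estimation from purity and local copy number, Dirichlet-process
    clustering of mutations across regions, exhaustive sum-rule clone-tree
    enumeration with BIC model selection, topology classification, somatic
    copy-number event calling (arm and chromosome loss, CN-LOH, homozygous
    deletion, mirrored subclonal allelic imbalance), cohort-level repeated
    evolutionary trajectory inference by transfer learning with jackknife
    stability, simplified dN/dS selection scans, mutational-signature
    exposure fitting, neoantigen filtering, HLA loss-of-heterozygosity
    calling, and the survival and association statistics used in
    multi-region mesothelioma studies. A synthetic multi-region cohort
    simulator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    rpart,
    pracma,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape,
    withr
Config/testthat/edition: 3
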