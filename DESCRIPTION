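Package: depscan
Title: Detection of Cancer Genetic Dependencies from Loss-of-Function Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates loss-of-function screens (siRNA, shRNA, CRISPR) in
    tumor cell line panels with genotype calls for cancer driver genes to
    detect cancer genetic dependencies: gene inhibitions to which
    driver-altered cell lines are selectively sensitive. Functional
    alterations are called from mutation and gene-level copy-number tables
    using oncogene and tumor-suppressor rules; each driver-target-context
    combination is tested with a one-sided Mann-Whitney U test and a
    common-language effect size, filtered at published thresholds, and
    annotated with functional-interaction tiers, inhibitor availability,
    and cross-dataset support. A synthetic-fixture generator makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, FunctionalGenomics, CellBasedAssays, StatisticalMethod
RoxygenNote: 7.3.3
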