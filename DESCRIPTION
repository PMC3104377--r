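Package: xbias
Title: Tissue-Bias Scoring and X-Chromosome Representation Analysis for
    Drosophila Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies tissue bias of gene expression with a minimal
    target-to-panel signal ratio, tests over- and under-representation of
    gene sets on Drosophila chromosome arms (hypergeometric, Fisher exact,
    chi-square with Bonferroni or FDR control), analyses testis-development
    expression time courses with empirical-Bayes moderated t statistics,
    relates developmental up-regulation to chromatin-protein binding
    profiles, and ships a synthetic-data generator with planted effects so
    every stage has a parameter-recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
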