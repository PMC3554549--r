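Package: bomp
Title: Hybrid Burden and Mutation-Position Likelihood Test for
    Case-Control Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the BOMP (Burden Or Mutation Position) hybrid
    likelihood test for rare-variant case-control association: a
    directional collapsing burden statistic with a data-driven burden
    threshold, a non-directional windowed mutation-position multinomial
    statistic with segmentation selection, their combination into a
    single log-likelihood ratio, and permutation p-values (optionally
    stratified) with Benjamini-Hochberg adjustment across functional
    groups (genes or gene sets).  Also provides an etiology-driven
    simulation framework for extreme-phenotype case-control studies
    (allele-frequency-spectrum models, Gaussian liability traits,
    eight disease etiologies including key-region clustering and
    protective variants) and power estimation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
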