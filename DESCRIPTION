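Package: csea
Title: Custom Set Enrichment Analysis and Intersecting-Set Sankey Diagrams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enrichment analysis of arbitrarily ranked feature lists against
    user-defined custom sets via a weighted Kolmogorov-Smirnov running-sum
    statistic, with set-permutation empirical p-values, normalized enrichment
    scores, multiple-testing correction, a hypergeometric over-representation
    test for unranked selections, and a significance-annotated set-by-phenotype
    summary figure. Also builds three-layer (level - feature - task)
    intersecting-set Sankey graphs from coefficient arrays produced by
    multitask multilevel regression models and exports them as self-contained
    interactive HTML with a lossless JSON sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
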