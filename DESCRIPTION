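Package: parallevo
Title: Pleiotropy, Ancestral Variation and Parallel Gene Expression Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the parallelism of gene
    expression evolution across replicated experimental-evolution
    populations and dissecting its determinants. Provides TMM/CPM
    normalization and negative-binomial differential-expression testing
    (via edgeR), the per-gene parallelism statistic 1/F based on a one-way
    analysis of variance of per-sample log2 fold changes, pleiotropy
    proxies (tissue-specificity index tau and regulatory-network
    connectivity), Gaussian causal-model selection by BIC over five causal
    graphs relating pleiotropy, ancestral expression variation and
    parallelism, path-analysis decomposition of direct and indirect
    pleiotropic effects, a synthetic-data generator with known causal
    ground truth, and a forward Wright-Fisher simulator of replicated
    polygenic adaptation after an optimum shift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    edgeR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
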