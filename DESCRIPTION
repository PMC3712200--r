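Package: dosepath
Title: Dose-Response Expression Pattern Mining and Pathway Activity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for dose-response transcriptomics of
    treated cell lines. Implements microarray preprocessing (background
    filtering, quantile normalization, probe collapsing, log-ratio
    computation), short-series expression-profile mining over ordered dose
    points with permutation false discovery rates, hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction, topology-based
    signaling pathway impact analysis (over-representation and perturbation
    evidence combined into a global p-value), signed linear pathway-activity
    scoring with a permutation null and hierarchical clustering, Jaccard
    pathway-similarity matrices, and univariate Cox survival-gene screening
    with permutation p-values and pattern-versus-hazard contingency tests.
    Ships synthetic-data generators that emulate the full study design so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
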