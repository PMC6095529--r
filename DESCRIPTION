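Package: shapescission
Title: Analysis of Material and Shape-Transformation Categorization Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing behavioural experiments in which observers
    judge the material of photographed objects and the shape-transforming
    process ("causal history": twisted, crumpled, bent, folded) that produced
    their current shape. Provides a long-format trial-table data model for
    free-naming, rating and four-alternative forced-choice tasks; confusion
    matrices with explicit semantics; the perf distance statistic against a
    perfect prediction matrix with bootstrap confidence intervals and a
    random-prediction-matrix null; inter-observer consistency; two-way
    repeated-measures ANOVA with Huynh-Feldt sphericity correction and
    post-hoc paired t-tests; PCA of rating profiles with a silhouette-based
    separability score quantifying the scission of material and
    transformation information; and a generative observer simulator so the
    entire pipeline runs on synthetic data.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
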