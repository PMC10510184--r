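Package: clonevo
Title: Tumor Heterogeneity and Clonal Evolution in Paired Pre/Post-Treatment Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired pre- and post-treatment tumor exome
    cohorts: somatic variant filtering with per-criterion attrition reports,
    six per-sample heterogeneity indices (TMB, CNA burden, wGII, MATH, Shannon
    diversity, subclone count), Dirichlet-process binomial mixture clustering
    of variant allele fractions with purity and copy-number correction,
    exhaustive clone-tree inference under the subclonal sum rule,
    classification of each patient into a homogeneous- or heterogeneous-origin
    clonal evolution model, repaired/new mutated-gene overlap analysis, exact
    Wilcoxon rank-sum cohort comparisons, and a synthetic paired-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    ggplot2,
    generics,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
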