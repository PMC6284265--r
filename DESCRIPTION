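Package: longsamgsr
Title: Longitudinal Gene Expression Feature Selection via Gene Set Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects phenotype-relevant genes from longitudinal case/control
    expression experiments by treating each gene's trajectory across time
    points as a gene set. Per-gene, per-time-point SAM statistics are combined
    into a sum-of-squares gene-set statistic, screened by subject-level
    permutation testing with false-discovery-rate control, and each selected
    gene is reduced to the core time points driving its association, with the
    reduction cutoff tuned by stratified cross-validation. Includes
    per-time-point linear support vector machine evaluation with averaged
    posterior probabilities (misclassification error, generalized Brier score,
    belief confusion metric, area under the precision-recall curve), and a
    simulator of longitudinal expression studies with logit-generated binary
    outcomes for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
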