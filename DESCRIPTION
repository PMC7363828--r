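Package: oscca
Title: Objective-Specific Sparse Canonical Correlation Analysis for
    Imaging Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Three-way sparse canonical correlation analysis in which the
    third data block is a scalar study objective (e.g. age at onset), so
    that imaging-genetic, genetic-target and imaging-target associations
    are maximized jointly.  Provides the alternating soft-threshold
    solver, nested five-fold cross-validated feature selection with
    random-forest prediction of the target, LASSO and minimum-redundancy
    maximum-relevance comparison selectors, SNP quality-control
    arithmetic (minor allele frequency, call rate, exact Hardy-Weinberg
    test, genotype-quality masking), hypergeometric over-representation
    analysis of selected variants, and a synthetic-data generator with
    planted sparse cross-modal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
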