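Package: frontsig
Title: Invasion-Front and Bulk-Tumor Gene-Module Signatures for Early
    Relapse in Stage IIA MSS Colon Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and application of prognostic gene-expression
    signatures for early relapse in stage IIA microsatellite-stable colon
    cancer. Implements bootstrap-stability screening of per-gene
    Mann-Whitney AUCs, construction of signed gene modules from gene-set
    collections (GMT), elastic-net classification on module scores inside
    an external leave-one-out loop, combination of matched bulk-tumor and
    invasion-front classifier scores, exact cohort statistics (Fisher
    exact test, pooled t-test, Clopper-Pearson intervals), the three
    published frozen signatures, and a synthetic paired-cohort generator
    for end-to-end testing without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
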