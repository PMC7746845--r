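Package: reosig
Title: Relative Expression Ordering Gene-Pair Signatures for Drug Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting drug-resistant/sensitive cell-line models that
    represent clinical tumour tissue and for building rank-based
    (relative expression ordering, REO) gene-pair signatures that predict
    treatment outcome from a single expression profile. Implements SAM-style
    permutation differential expression, univariate Cox screening of genes and
    of within-sample gene-pair order indicators, exact binomial tests for the
    sign-concordance of gene lists, hypergeometric gene-set over-representation,
    Harrell's C-index driven exhaustive signature optimisation with a
    majority-vote risk rule, and a synthetic-data generator that emulates
    matched cell-line/tissue cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
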