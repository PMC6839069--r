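Package: clonalmix
Title: Random-Effects Estimation of the Proportion of Clonally Related
    Tumor Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the population proportion of patients whose two
    tumors are clonally related (one a metastasis of the other) from
    somatic-mutation match data.  Each patient contributes the set of
    loci mutated in at least one tumor of the pair, with known
    per-mutation occurrence probabilities; matches at rare loci carry
    strong evidence of clonality.  The model is a two-component
    random-effects mixture: with probability pi a case is clonal and its
    anticipated fraction of matched mutations (the clonality signal) is
    drawn from a lognormal law, otherwise the tumors are independent.
    Two estimators are provided: direct box-constrained quasi-Newton
    maximization of the marginal likelihood, and an EM algorithm over
    the latent clonality indicator and signal that avoids spurious
    boundary estimates of pi.  Includes per-case posterior clonality
    probabilities, a model-faithful simulator with a study runner for
    estimator comparison, readers and writers for a simple per-locus
    TSV format, and a packaged 49-case contralateral breast cancer
    example dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
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
    withr,
    yaml
Config/testthat/edition: 3
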