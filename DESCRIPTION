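Package: softvote
Title: Probability-Averaging Ensembles and Inter-Learner Agreement Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combine the class-confidence vectors of independently trained
    classifiers by arithmetic or geometric averaging (equivalently the product
    rule), and diagnose why the ensemble outperforms its members: mean pairwise
    similarity of confidence vectors, right/wrong agreement-pattern histograms
    (RRR, RRW, RWW, WWW for three learners), rescue analysis of samples where
    only one learner is correct, and top-1 confidence profiles. Includes a
    latent-Gaussian-logit generator of correlated synthetic learner cohorts
    with independent controls for accuracy, inter-learner correlation and
    confidence peakedness, so the whole pipeline is testable without trained
    models, plus an end-to-end reporting pipeline and command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
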