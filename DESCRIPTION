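Package: cigame
Title: Collective Investment Games and Stalk Allocation in Social Amoebae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing public-goods cooperation in aggregative
    multicellular microbes such as Dictyostelium discoideum. Implements the
    Collective Investment game with relatedness-dependent optimal stalk
    investment, Gaussian perception error integrated by quadrature, and a
    transdifferentiation (negative-feedback) enforcement term; converts
    spore-count assays to inferred stalk investment and back; fits the game to
    per-composition investment data by grid search with parametric-bootstrap
    confidence intervals, nested-model F tests and goodness-of-fit summaries;
    classifies cell fates from smFISH transcript counts via a normalised pspA
    index; provides fruiting-body collapse statistics and low-frequency
    enforcement comparisons; and generates synthetic assay-shaped datasets so
    the whole pipeline is testable end to end.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
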