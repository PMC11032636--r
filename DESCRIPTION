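Package: sizeform
Title: Form Typicality of Semantic Size from Pronunciation Lexicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Derives surface-form variables (phoneme class counts, initial and
    final phoneme features, stress position) from ARPAbet pronunciations,
    selects a best-subset linear model of semantic size ratings under Mallow's
    Cp via an exact branch-and-bound search, and scores each word's z-scored
    fitted value as its form typicality. Includes Welch ANOVA with
    Games-Howell post hoc comparisons across lexical categories, three-step
    hierarchical regressions with heteroskedasticity-consistent standard
    errors for item-level behavioural outcomes, and a seeded synthetic lexicon
    generator with planted effects for end-to-end validation.
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
    Rcpp,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    caret,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
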