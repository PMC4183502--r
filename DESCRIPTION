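Package: nnindep
Title: Independence Tests from Exact Nearest-Neighbour Distance
    Distributions on the Rank Torus
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact joint, conditional and marginal distributions of the
    i-th nearest-neighbour Chebyshev distances of rank-transformed
    bivariate samples on a discrete torus, obtained by closed-form
    counting of admissible point configurations, with enumeration and
    Monte-Carlo validators.  Provides two nonparametric tests of
    independence built on these distributions (a chi-squared
    distributional test and an extreme-path location test) and a
    mutual-information-calibrated benchmark framework of functional
    dependencies and patchwork copulas for comparing independence tests
    by empirically calibrated power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    energy,
    Hmisc,
    minerva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
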