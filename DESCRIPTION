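Package: coalafs
Title: Expected Allele Frequency Spectra for Populations with Arbitrarily
    Varying Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the expected allele frequency spectrum (site frequency
    spectrum) of a sample from a single population whose haploid size varies
    arbitrarily through backward time, by rescaling the Kingman coalescent
    with the cumulative rate function g(t) = integral of 1/N(u) and
    numerically inverting it.  Provides constant, exponential, logistic,
    Gompertz and piecewise-constant demographies; three interchangeable
    inversion schemes (a generation-stepping finite-sum scan, bracketed
    root-finding on g, and closed forms including a Lambert-W inverse for
    logistic growth); overflow-safe log-gamma spectrum combinatorics valid
    for thousands of haplotypes; a seeded Monte-Carlo coalescent sampler for
    validation; and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
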