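Package: clonedyn
Title: Lifelong T Cell Clone-Size Dynamics and Repertoire Imprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulators, closed-form theory, and statistical tooling
    for the dynamics of T cell receptor (TCR) clone sizes across the human
    lifespan. Implements exact (Gillespie) and mean-field birth-death-immigration
    simulations of repertoire formation under competition for proliferation
    signals, a geometric Brownian motion model of fluctuating clonal selection,
    subsampling-robust discrete power-law maximum likelihood estimation of
    clone-size exponents via the Hurwitz zeta function, a synthetic-cohort
    generator with statistical clone dating based on zero-insertion VDJ
    recombination statistics, rank-binned zero-insertion enrichment analysis
    with weighted sigmoid fitting, and longitudinal clone-size fluctuation
    estimation. Results are returned as tibbles; fitted objects carry
    broom-style tidy() and glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
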