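Package: matriline
Title: Maternally Inherited Sex-Ratio Variation and Endosymbiont Effects in
    Pedigreed Broods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes among-female variation in brood (clutch) sex ratio
    into a maternally inherited component and a residual dam-level component
    with a Bayesian logit-Bernoulli "maternal animal model" fitted by
    Metropolis-within-Gibbs sampling. Includes a forward-time pedigree
    simulator with endosymbiont transmission and sex-ratio-distorting
    mechanisms (male killing, feminization), exact tests and weighted
    correlations for endosymbiont prevalence and clutch-size diagnostics,
    quadrature oracles for validating the sampler, and CSV/JSON/YAML
    interfaces with a small command-line front end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
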