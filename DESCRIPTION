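Package: nnowiw
Title: Neutrosophic New Odd Weibull-Inverse Weibull Lifetime Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distribution functions, moments, entropies, and quantiles for the
    new odd Weibull-inverse Weibull (NOWIW) lifetime distribution together
    with its neutrosophic (interval-valued) extension, in which parameters
    and observations carry an explicit indeterminacy interval. Provides
    maximum likelihood, least squares, and weighted least squares fitting of
    point-valued and interval-valued samples, a registry of competing
    inverse-Weibull-family models, information criteria and goodness-of-fit
    statistics (Kolmogorov-Smirnov with exact small-sample p-values,
    Anderson-Darling, Cramer-von Mises), a seeded Monte Carlo harness for
    estimator evaluation, and a bundled interval-valued battery-lifetime
    dataset.
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
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
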