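Package: pmqlreg
Title: Liu and Ridge Shrinkage for the Poisson-Modification of Quasi
    Lindley Regression Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the Poisson-Modification of Quasi Lindley (PMQL)
    log-linear regression model for overdispersed count responses by
    iteratively weighted least squares, and stabilises the fit under
    multicollinearity with Liu and ridge shrinkage estimators. Provides
    the PMQL probability law (density, moments, random generation),
    shrinkage-parameter selectors, scalar mean square error (SMSE)
    theory with matrix-superiority checks, and a Monte Carlo engine
    that estimates the SMSE of the competing estimators over factorial
    simulation designs. Results are returned as tibbles with
    broom-style tidy() and glance() methods and ggplot2 autoplot()
    graphics.
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
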