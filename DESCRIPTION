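Package: zihurdle
Title: Zero-Inflated and Hurdle Count Regression with Zero-Deflation
    Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood fitting of zero-inflated (ZIP, ZINB) and
    hurdle (hurdle-Poisson, hurdle-NB) count regression models with a logit
    link on the zero component and a log link on the count component,
    alongside plain Poisson and negative binomial fits.  Provides randomized
    quantile residuals with Shapiro-Wilk adequacy testing, the Vuong test and
    AIC differences for non-nested model comparison, zero-deflation
    diagnostics (per-observation deflation indicators, deflation percentages
    and surfaces), standardized differences between structural-zero and
    sampling-zero probabilities, the exact hurdle-to-zero-inflated parameter
    mapping and its inverse, and a seeded factorial simulation-study engine
    comparing the two model families on relative (AIC, Vuong) and absolute
    (residual normality) fit criteria.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
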