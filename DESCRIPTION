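Package: twinaging
Title: Lifestyle Behaviour Classes and the Genetics of Biological Aging in Twin Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking adolescent lifestyle behaviour patterns to
    epigenetic measures of biological aging in twin data. Implements latent
    class analysis of mixed ordinal and continuous indicators by EM with
    full-information maximum likelihood for missing items, class-enumeration
    statistics (AIC, BIC, sample-size-adjusted BIC, Vuong-Lo-Mendell-Rubin
    and Lo-Mendell-Rubin tests, average posterior probabilities), the
    Bolck-Croon-Hagenaars three-step distal-outcome estimator with
    cluster-robust inference, univariate twin variance-component models
    (ACE, ADE, AE, CE, E) with FIML for incomplete pairs, and the
    decomposition of outcome variance into genetic and environmental
    components shared with the latent lifestyle classes. Includes a
    genetically structured synthetic twin-cohort generator with closed-form
    and simulation ground truth for every downstream estimator.
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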