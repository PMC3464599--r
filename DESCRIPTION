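Package: mokkenscale
Title: Nonparametric Item Response Theory Scale Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mokken scale analysis for binary and ordinal questionnaire
    items: Loevinger scalability coefficients (H_ij, H_i, H and the
    transposed-matrix coefficient H^T), automated item selection into
    unidimensional scales (aisp), manifest monotonicity diagnostics
    against restscore groups, invariant item ordering (MIIO) diagnostics
    with backward item removal, and Molenaar-Sijtsma total-score
    reliability alongside Cronbach's alpha. Includes a latent-trait
    simulator so every diagnostic can be exercised on data with known
    structure. Functions take a data frame of item scores and return
    tibbles or tidy-able result objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
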