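Package: morphogap
Title: Morphological Discontinuity Detection for Species Delimitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Pairwise detection of morphological discontinuities between
    putative species using normal-theory statistical tolerance regions.
    Bivariate trait spaces (e.g. leaf length by leaf width) are compared
    along the ridgeline manifold of the two-component normal mixture
    implied by each species pair; univariate count traits (e.g. flowers
    per inflorescence) are compared with one-sided tolerance limits built
    from noncentral-t quantiles. Includes specimen-table ingestion and
    aggregation, Monte Carlo calibration of bivariate tolerance factors,
    a synthetic specimen-panel generator emulating herbarium trait data
    for the shrub genus Escallonia, an end-to-end decision pipeline, and
    ggplot2 graphics for tolerance-coverage profiles.
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
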