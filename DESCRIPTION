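Package: fatrophic
Title: Fatty-Acid Trophic Analysis for Symbiotic Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating the trophic strategies of symbiotic corals
    from fatty-acid composition profiles (percent of total fatty acids).
    Provides fatty-acid nomenclature parsing and profile validation, three
    established trophic biomarker indices (18:1n-7/18:1n-9 ratio,
    photosynthetic vs animal-derived input, sum of long-chain MUFA),
    distance-based permutation statistics (PERMANOVA with crossed factors,
    pairwise tests, PERMDISP), principal component analysis with variable
    contributions, host-symbiont per-fatty-acid regressions, and a
    bootstrap linear-discriminant-analysis procedure that estimates the
    proportional contribution of polyunsaturated fatty-acid sources
    (endosymbionts, copepods, phytoplankton groups) to coral host tissue.
    Includes a compositional synthetic-data generator for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    vegan
Suggests:
    testthat (>= 3.0.0),
    MASS,
    readxl,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
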