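Package: clearcv
Title: Quantifying the Uniformity of Tissue-Clearing Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the expansion that hydrogel-based tissue
    clearing (CLARITY-style protocols) induces in brain tissue and to test
    whether that expansion is uniform across brain regions and spatial
    scales. Implements the adjusted expansion ratio (relative change in a
    measure normalised to one spatial dimension by its d-th root), the
    clearing coefficient of variation across measures, and an acceptability
    threshold derived from the natural variability of the same anatomical
    measures in uncleared tissue. Includes a seeded synthetic-tissue
    simulator (spatial Poisson cell fields, rendered 3D image stacks,
    antibody-penetration time series), deterministic measurement operators
    (plane-intersection cell density, threshold-and-label 3D volumetry,
    cortical thickness, penetration depth), a saturating-exponential
    antibody-penetration model fit, and an end-to-end seeded study pipeline
    with Welch tests and Shapiro-Wilk normality gates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
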