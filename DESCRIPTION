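Package: paleocensus
Title: Fossil Leaf-Census Analysis of Plant and Insect-Herbivore Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of fossil dicot leaf censuses:
    reading and validating leaf-level census tables with insect damage-type
    (DT) scoring, pooling quarries into stratigraphic levels, floral
    diversity and evenness (Shannon, Pielou), rank abundance,
    individual-based rarefaction of plant species and of damage types
    (including undamaged leaves and leaves bearing multiple DTs in the
    resampling universe), damage frequency and specialized-to-generalized
    feeding ratios, leaf-margin paleotemperature and leaf-area
    paleoprecipitation proxies, and nonmetric multidimensional scaling of
    unit-by-species and unit-by-DT count matrices. Includes a synthetic
    census generator so the whole pipeline is testable without specimen
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
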