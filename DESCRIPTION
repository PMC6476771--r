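Package: fruitniche
Title: Habitat Selection and Fruit Preference Analysis for Sympatric Frugivores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how sympatric frugivores (western lowland
    gorillas and central chimpanzees) partition habitat and fruit resources.
    Implements Manly design-1 selectivity ratios with chi-squared
    goodness-of-fit tests and Bonferroni-adjusted preference classification
    from nest surveys; a fruit preference scoring stack that combines stem
    density, a phenology- and basal-area-based Fruit Availability Potential,
    fecal seed-count diet reconstruction (Mean Consumption Score) and a
    Global Importance Score ranking; seasonal fallback-food determination and
    collapse to plant consumption traits; correspondence analysis of
    trait-by-habitat abundance tables; and PERMANOVA with dispersion
    homogeneity tests on Bray-Curtis dissimilarities. A seeded synthetic-data
    generator emulates the full field design (transect availability surveys,
    nest records, fecal samples, phenology, botanical plots) with known
    ground truth for parameter-recovery testing.
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
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
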