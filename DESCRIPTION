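Package: smtz
Title: Sediment Sulfate-Methane Transition Zone Geochemistry and
    Community Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing coastal sediment porewater geochemistry and
    16S rRNA gene amplicon communities around the sulfate-methane transition
    zone (SMTZ). Converts headspace gas-chromatograph methane readings to
    total porewater concentrations by the headspace equilibration method,
    fits linear sulfate gradients to estimate the depth of no sulfate and
    porosity/tortuosity-corrected diffusive fluxes by Fick's first law,
    summarises seasonal temperature records and methane fold changes between
    seasons and bays, and performs family-level aggregation, Bray-Curtis
    dissimilarity, principal coordinates analysis and permutational
    multivariate ANOVA on amplicon count tables. A synthetic-data generator
    emulates porewater profiles, temperature logger series, headspace jars
    and depth/bay-structured communities with known ground truth so the
    whole chain is testable end to end.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
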