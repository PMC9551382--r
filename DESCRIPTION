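Package: spermFISH
Title: Sperm FISH Aneuploidy and Meiotic Segregation Analysis for
    Robertsonian Translocation Carriers
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multicolor sperm fluorescence in situ hybridization
    (FISH) aneuploidy studies in carriers of the Robertsonian translocation
    der(13;14)(q10;q10). Encodes the meiotic segregation of the der(13;14)
    trivalent (alternate, adjacent, 3:0) and the mapping from segregation
    products to expected FISH signal patterns; classifies per-nucleus signal
    counts into numerical-abnormality categories and segregation-mode calls,
    using a tri-color ploidy-control probe to separate diploid sperm from
    3:0 products; aggregates per-chromosome and per-carrier frequency
    tables; and performs the carrier-versus-control statistical comparisons
    (paired t, two-proportion, one-way ANOVA with Student-Newman-Keuls,
    Kruskal-Wallis with Steel-Dwass, and a binomial GLM with Bonferroni
    contrasts). A seeded synthetic-cohort generator reproduces the study
    design so every stage is testable without access to raw slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
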