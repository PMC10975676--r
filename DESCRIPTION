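Package: vmrtox
Title: Visual Motor Response, Dose-Response and Lipidomic Analysis for
    Zebrafish Embryo Toxicology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for larval zebrafish visual motor response
    (VMR) assays and companion toxicological endpoints. Corrects the two
    classes of centroid-tracking artifacts seen in multi-well video
    tracking, segments beat-and-glide swimming bouts, and computes ten
    general and four startle-specific behavioral endpoints per embryo.
    Inference uses one-way nonparametric permutation ANOVA with a
    sequential standard-error stopping rule (linear and binomial
    responses) followed by Tukey honest significant difference
    comparisons. Also provides probit LC10/LC50 estimation from
    dose-mortality tables, concentration unit conversion and recovery
    arithmetic, lipidomics quality-control filtering and wet-weight
    normalization, and trend-table construction for lipid species. A
    seeded synthetic-data generator emulates larval swim tracks in
    circular wells under a light/dark schedule, tracking artifacts,
    probit mortality, and lipid pools with planted effects, so every
    pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
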