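Package: clonetrial
Title: Quantitative Genetics of Clonal Field Trials and Seed-Oil Quality
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of randomized-block clonal trials in tree-breeding
    programs: per-trait ANOVA and variance components, phenotypic and
    genotypic coefficients of variation, broad-sense heritability, genetic
    advance under selection, genotypic/phenotypic/environmental correlation
    matrices from mean cross-products, path-coefficient decomposition of
    trait correlations with a target trait, and Duncan's multiple range test
    with compact letter display.  Includes a seedable multi-trait trial
    simulator with known genetic ground truth, packaged reference tables
    from a published Jatropha backcross hybrid clonal trial, and titration
    based seed-oil quality indices (acid value, free fatty acid percent,
    saponification number, iodine value, predicted cetane number) with
    biodiesel-standard compliance checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, stats, utils
Suggests: jsonlite, testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
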