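Package: staygreen
Title: Spatiotemporal Modeling of Canopy Senescence and Haplotype Discovery
    for Stay-Green in Barley
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An analysis pipeline for characterizing the stay-green
    (delayed post-anthesis senescence) phenotype in cereal breeding panels
    from multi-temporal canopy reflectance (NDRE) measured over field
    trials.  Provides two-dimensional P-spline (SpATS-style) and
    AR1xAR1 linear-mixed-model spatial correction of plot-level data with
    heritability-based model selection; three-level hierarchical P-spline
    growth curves over thermal time with analytic derivatives and
    area-under-the-curve trait extraction; factor-analytic
    multi-environment REML analysis with interaction-class (iClass)
    derivation and kinship-based genetic correlation to yield; and
    haplotype discovery via linkage-disequilibrium blocks, ridge-regression
    BLUP marker effects, local genomic estimated breeding values
    (localGEBVs) and in-silico haplotype stacking.  A synthetic trial
    generator with ground-truth accessors supports parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    mgcv,
    splines,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
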