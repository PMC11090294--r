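Package: ailqtl
Title: Dissection of Polygenic QTL Regions in Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of a polygenic
    quantitative trait locus (QTL) region in a multigenerational advanced
    intercross line (AIL). Implements single-marker and conditional
    association scans with sex and generation fixed effects,
    variance-heterogeneity scans based on the Brown-Forsythe test,
    haplotype-block and ancestry-class association, the natural and
    orthogonal interactions (NOIA) decomposition of additive, dominance and
    epistatic effects with frequency-adjusted design matrices,
    genotype-stratified conditional scans for masking epistasis, and
    conservation/annotation-based candidate-variant prioritization. A
    configurable AIL simulator (divergent founder lines, Haldane meiosis,
    additive/dominance/epistatic/variance-heterogeneity trait architectures)
    provides synthetic cohorts for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
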