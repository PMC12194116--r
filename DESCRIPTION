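Package: EchoDose
Title: Quantitative Ultrasound Dose-Response Analysis for Percutaneous
    Electrolysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the dose-dependent structural changes that
    galvanic current induces in muscle tissue, as seen on B-mode ultrasound.
    Provides a synthetic B-mode image generator (Rayleigh speckle with
    dose-dependent hyperechoic foci and posterior acoustic shadowing),
    segmentation of affected areas with geometric and echotexture features
    (GLCM, gray-level difference statistics, Haar detail statistics), and a
    dose-response statistical stage: Spearman screening, per-feature and
    backward-elimination multiple regression, a composite electrolysis dose
    index, and Kruskal-Wallis group comparison with Bonferroni-corrected
    Mann-Whitney post hocs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
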