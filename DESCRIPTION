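Package: SpindleDots
Title: Dot-Chromosome Spindle Position Measurement and Comparative
    Cytology Statistics for Drosophila Female Meiosis I
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the behaviour of the small "dot" (Muller F)
    chromosomes during Prometaphase I in Drosophila oocytes from
    single-channel confocal z-stacks: maximum-intensity projection,
    automated "out on the spindle" classification by a 50 percent dip in
    background-subtracted intensity along a line profile, XY outer-edge
    distance, light-cone Z localisation, 3D dot-dot separation via the
    Pythagorean theorem, and cross-sectional chromosome area. Includes a
    synthetic confocal-stack and species-table generator with ground
    truth for validation, and the comparative statistical layer: species
    summaries, pairwise inversion-type contrasts with a step-up false
    discovery rate procedure using Q = 1/(2m), group mean comparisons,
    Pearson correlations with regression significance, and phylogenetic
    pair-averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, Classification, Software
RoxygenNote: 7.3.3
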