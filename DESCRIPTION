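Package: equilunge
Title: Posture Morphometrics and Thermographic Pixel Counting for Lunged Horses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the postural and body-surface-temperature
    response of horses to lunging with different lunging aids. Implements a
    semilandmark dorsal-profile pipeline (TPS input, 30-point curve built
    from eight anatomical anchors, Generalized Procrustes Analysis,
    principal component analysis of Procrustes coordinates, Goodall-style
    Procrustes ANOVA for shape and one-way ANOVA for centroid size,
    per-class consensus shapes and 0.9-probability confidence ellipses) and
    a thermographic Pixel-Counting Protocol (pseudocolor rendering of
    temperature fields over 28-38 degrees C, exact #000000 background
    masking, CIELAB CIE76 nearest-reference color grouping into five 2
    degree bins, per-bin pixel percentages, Kruskal-Wallis and Dunn
    comparisons). A synthetic-data generator emulates the study design (13
    horses x 4 conditions x 2 time points) so every stage is testable
    without the original images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    farver,
    vegan
Config/testthat/edition: 3
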