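Package: germlapse
Title: Quantitative Scoring of Fission Yeast Spore Germination from
    Segmented Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify Schizosaccharomyces pombe spore germination
    and spore health from time-lapse stacks of segmented label masks:
    equivalent-ellipse morphometry (area, aspect ratio), overlap-based object
    tracking with focus-loss handling, first-division calling from the
    aspect-ratio criterion, germination efficiency, swelling-window detection,
    rule-based classification of outgrowth phenotypes (normal, elongated,
    bubble, bipolar, exploded), partitioning of vacuole (FM4-64) fluorescence
    between spore body and germ-tube outgrowth, and colony-forming-unit
    longevity and acute-stress statistics (trapezoidal area under the
    viability curve, t-tests, Fisher's exact test, one-way ANOVA with post hoc
    comparisons). A seeded synthetic-data generator produces label-mask
    stacks, fluorescence channels, and plate-count tables with full ground
    truth for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
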