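Package: rheotax
Title: Quantification of Rheotaxis, Folate Chemotaxis and Lysosome
    Exocytosis in Dictyostelium
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory statistics (net X displacement, speed, directional
    persistence), parallel-plate flow-chamber shear-stress physics,
    micropipette and agar chemotaxis metrics, exocytic membrane-patch
    scoring in fluorescence images, and replicate-level statistical
    comparison for shear-flow migration (rheotaxis) studies in
    Dictyostelium amoebae. Includes a synthetic-data generator (biased
    persistent random walks, detection streams, labelled-cell images)
    emulating the experimental design so every stage of the pipeline is
    testable without raw movies, plus a greedy nearest-neighbour
    detection linker standing in for commercial particle tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Software, ImmunoOncology
RoxygenNote: 7.3.3
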