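Package: nucscreen
Title: Imaging-Based siRNA Screen Analysis for Nuclear Size and Shape
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for imaging-based high-content siRNA screens
    of nuclear morphology. Generates fully ground-truthed synthetic screens
    (384-well layouts, per-nucleus morphometry tables, rendered multichannel
    nucleus images), segments nuclei from DAPI images and measures per-nucleus
    geometry (area, major/minor axis, Crofton perimeter, circularity =
    4*pi*Area/perimeter^2) and lamin A/C / lamin B1 intensities, normalizes
    per-well means with per-plate B-scores (Tukey median polish) and
    per-replicate robust Z-scores, and calls gene-level hits by the
    median-of-three-oligos rule with cell-number viability exclusion.
    Includes two-sample Kolmogorov-Smirnov and Spearman statistics for
    single-cell distribution comparisons between conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBasedAssays, ImageCytometry, Normalization, Software
RoxygenNote: 7.3.3
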