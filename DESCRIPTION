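Package: mitospindle
Title: Quantification of Mitotic Spindle Orientation and Astral
    Microtubule Censuses in Developing Neocortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image cytometry of mitotic neural progenitors in the developing
    mouse neocortex: chromosome-plate orientation tracking and its maximal
    amplitude statistic, regional censuses of cortex-reaching astral
    microtubules (apical/central/basal for apical progenitors, orientation
    classes for basal progenitors), cortical-marker (LGN) intensity
    profiling along the normalized cell perimeter, spindle-integrity
    metrics, classification of divisions as bisecting or bypassing the
    apical membrane domain, and tissue-level censuses by cortical zone.
    Includes a ground-truthed synthetic fluorescence-microscopy generator
    (mitotic cells, mean-reverting plate-angle trajectories, tissue scenes)
    so every quantification can be validated by parameter recovery, and the
    statistical summaries and tests used with these measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
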