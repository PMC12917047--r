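Package: musctrack
Title: Motility, Registration and Lineage Analysis of Live-Imaged Muscle Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-lapse tracks of muscle stem cells
    (satellite cells) migrating on myofibres. Corrects cell trajectories for
    rigid fibre or tissue drift (landmark- and mask-based frame-to-frame
    registration with cumulative composition), computes per-track motility
    statistics (step speeds, net and total distance, straightness, turning
    angles), stratifies cells into mobile and static fractions at a
    migration-speed threshold, reconstructs lineage trees with
    symmetric/asymmetric division-mode and planar/perpendicular orientation
    classification, and derives differentiation and proliferation indexes and
    sister-cell co-migration statistics. A synthetic-data generator with
    wild-type and dystrophic (mdx) presets produces fibre drift, two-population
    persistent-random-walk trajectories, and stochastic lineages with full
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
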