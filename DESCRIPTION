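Package: asymdiv
Title: Mother-Restricted Division and Asymmetric Resource Segregation in
    Budding Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how budding yeast populations restrict
    division to mother cells under metal limitation by segregating a
    limiting vacuolar resource asymmetrically at cytokinesis. Provides a
    closed-form capacity model for symmetric versus asymmetric partitioning
    of a non-replenishable resource, a stochastic agent-based simulator of
    budding populations with regime presets (rich, low-zinc, whi5, vac17,
    zrc1-cot1), a synthetic dual-channel time-lapse renderer (nuclear and
    bud-neck markers plus label masks), an end-to-beginning tracking and
    lineage-reconstruction algorithm, and statistics for growth-mode
    classification, doubling times, size asymmetry, vacuole partition
    fractions and differential stress survival.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
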