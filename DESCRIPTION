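Package: pisascreen
Title: Hit Calling and Solubility Networks for PISA Thermal-Shift Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for large-scale proteome integral solubility
    alteration (PISA) chemical screens. Provides a synthetic screen generator
    built on two-state melting curves with thermal-window pooling, TMT channel
    sum normalization, the trimmed-standard-deviation nSD dual-cutoff hit
    calling framework with vehicle-based false-hit calibration, known-target
    assessment across cell and lysate modes, and all-by-all Spearman
    solubility correlation networks with kinome-group annotation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
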