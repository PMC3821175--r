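Package: synquant
Title: Quantification of Synaptic Transmission, Punctum Colocalization,
    and Docked-Vesicle Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolbox for synaptic physiology at the C. elegans
    neuromuscular junction: biexponential decomposition of evoked
    postsynaptic charge into fast and slow release components, 90-10%
    decay times and windowed charge transfer, sucrose-evoked
    readily-releasable-pool charges, miniature/tonic event detection and
    CALI illumination time courses, dual-channel immunofluorescence
    line-profile colocalization with a between-animal shuffled null, and
    docked-vesicle distance histograms from serial-section electron
    microscopy. Includes seeded synthetic-data generators with ground
    truth for every stage, group statistics (mean +/- SEM, Student's t,
    one-way ANOVA with Student-Newman-Keuls post hoc), and a
    config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
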