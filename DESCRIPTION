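Package: rpewave
Title: Sine-Wave Quantification of Optic Disc Tilt from Circumpapillary
    OCT Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies optic disc tilt by fitting a sine wave to the
    course of the retinal pigment epithelium (RPE) in circumpapillary
    optical coherence tomography (OCT) circle-scan B-images. The fitted
    amplitude is the tilt metric. Includes the modified ovality ratio of
    the optic disc (with the 45-degree vertical/horizontal axis rule),
    reliability statistics (two-way absolute-agreement intraclass
    correlation with F-based confidence intervals), Spearman rank
    correlation, synthetic trace/image/cohort generators for end-to-end
    validation, and a batch pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    readxl,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
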