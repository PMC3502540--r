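Package: acthfcs
Title: ACTH Quantification by FCS Immunoassay and HPA-Axis Feedback Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies adrenocorticotropic hormone (ACTH) from fluorescence
    correlation spectroscopy (FCS) sandwich-immunoassay data via one- and
    two-component diffusion autocorrelation fitting, converts fitted particle
    numbers to molar concentrations through a calibrated confocal volume, and
    models glucocorticoid-mediated fast (membrane-receptor) and slow (genomic)
    negative feedback on ACTH secretion in anterior pituitary cells with two
    ordinary differential equation models fitted by Tikhonov-regularized
    global/local optimization. Includes a synthetic-data generator for the
    immunoassay protocol and a Brownian-dynamics photon-trace simulator with a
    multiple-tau correlator as an independent oracle for the analytic models.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
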