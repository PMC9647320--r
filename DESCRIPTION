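Package: airims
Title: Indoor Air VOC Profiling from GC-IMS Spectra
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for processing gas chromatography - ion mobility
    spectrometry (GC-IMS) measurements of indoor and ambient air: ion
    mobility constants (K, K0) and reactant-ion-peak (RIP) relative drift
    time normalization, simulation of spectra and multi-location sampling
    campaigns, automated 2D peak detection on the drift x retention time
    plane, compound identification against a packaged reference library of
    volatile organic compounds, and outdoor-normalized relative-intensity
    profiles per sampling location, including replicate stability reports
    and radar-chart displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
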