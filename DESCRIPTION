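Package: speckleflow
Title: Laparoscopic Laser Speckle Contrast Imaging Simulation and Perfusion Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for laser speckle contrast imaging (LSCI) of tissue
    perfusion. Implements the spatial sliding-window speckle contrast
    statistic (K = sigma/mean over a 7x7 window by default), conversion of
    contrast to laser speckle perfusion units (LSPU), underexposure masking,
    Viridis false-color perfusion maps with side-by-side white-light
    composition, relative-perfusion classification into well, marginally
    and poorly perfused tissue with demarcation-line extraction, and a
    physics-based dynamic speckle simulator (band-limited circular-Gaussian
    fields with per-pixel decorrelation times and finite-exposure
    integration) that provides ground-truth phantoms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    viridisLite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
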