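Package: nitrospec
Title: Leaf Nitrogen Estimation from Canopy Hyperspectral Reflectance at Multiple Leaf Layers
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating soybean leaf nitrogen concentration (LNC) at
    three vertical leaf layers (canopy, lateral, root) from field canopy
    hyperspectral reflectance (350-1830 nm). Implements Savitzky-Golay
    smoothing and first-derivative spectra, three classes of spectral
    parameters (empirical nitrogen-sensitive indices, "three-edge" derivative
    parameters, and ten dual-band index formulas), exhaustive two-band
    wavelength-pair correlation search, significance-based feature screening,
    and an estimation grid combining partial least squares regression, random
    forest, and a Levenberg-Marquardt-trained backpropagation network. A
    synthetic field-experiment generator emulates the two-year nitrogen-rate
    by rhizobium-inoculation trial that motivates the pipeline, so every stage
    is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
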