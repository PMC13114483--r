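Package: sfdibruise
Title: Simulation-Driven Spatial Frequency Domain Imaging for Subsurface
    Fruit Bruise Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spatial frequency domain imaging (SFDI) of turbid
    samples such as fruit tissue. Provides a diffusion-approximation forward
    model of spatially modulated diffuse reflectance, an analytic renderer
    that generates paired (reflectance, optical-coefficient) training data
    for planar and curved fruit-like scenes, three-phase demodulation with
    reference calibration, per-pixel nonlinear least-squares inversion of
    absorption and reduced scattering coefficients, four-step phase-shifting
    profilometry with surface-profile correction, a conditional adversarial
    U-Net translator with channel/spatial attention for fast coefficient
    prediction, image-quality metrics, and a two-step bruise discrimination
    layer built on the coefficient of variation, bruised-to-sound mean
    ratio, and ROC/Youden threshold selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    tiff,
    png,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
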