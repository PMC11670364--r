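Package: mvkvdect
Title: Simulation and Estimation-Theory Analysis of MV-kV Dual-Energy CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying dual-energy computed tomography performed
    with a detuned megavoltage treatment beam and a kilovoltage imaging
    beam, comparing energy-integrating and photon-counting detector
    models. Provides analytic polychromatic spectrum models, bundled
    mass-attenuation tables, Cramer-Rao lower-bound signal-to-noise
    analysis of two-material line integrals with dose-allocation
    optimization, procedural image-quality and torso phantoms, an
    equiangular fan-beam forward projector with per-energy-bin Poisson
    noise, sinogram-domain Gauss-Newton basis-material decomposition,
    fan-beam filtered back-projection, virtual monoenergetic image
    synthesis, and contrast-to-noise and noise-map analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    png
Config/testthat/edition: 3
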