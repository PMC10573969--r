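Package: pdlcreep
Title: Fiber-Content-Based Viscoelastic Creep Analysis of the Periodontal Ligament
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing nano-indentation creep experiments on the human
    periodontal ligament (PDL). Implements a standard-linear-solid (fiber spring in
    parallel with a Maxwell matrix branch) creep compliance, its generalized
    Kelvin-Voigt reparameterization, and a Schapery-form nonlinear strain response
    whose factors track collagen fiber content. Provides nonlinear least-squares
    fitting of hold-stage strain-time curves to recover the viscoelastic parameters
    (g0, g2, eta), Oliver-Pharr flat-punch reduced-modulus extraction from unloading
    data, collagen fiber content quantification from Masson-stained images, seeded
    synthetic-data generators emulating the full experimental protocol, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    tiff
Config/testthat/edition: 3
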