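Package: plasmopv
Title: Plasmonic Organic Photovoltaic Modelling for Epiretinal Prostheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale model chain for a plasmonic organic photovoltaic
    epiretinal prosthesis pixel: quasi-static optics of silver nanospheres
    embedded in a PCPDTBT:PCBM bulk heterojunction, coupled-dipole far-field
    spectra of a silver-nanoparticle cathode monolayer, Beer-Lambert light
    attenuation through the active layer, a three-term composite
    short-circuit photocurrent model with plasmonic near-field enhancement,
    a calibrated single-diode equivalent circuit with electrode load-line
    operating point, and a Hodgkin-Huxley axon cable driven by a
    method-of-moments plate-electrode field for activation-threshold
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
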