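Package: grenzrmf
Title: DNA Damage Spectra, RBE and OER Modelling for Grenz-Ray Radiobiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computational radiobiology of soft ("Grenz") X-rays.
    Provides a stochastic clustered-DNA-damage simulator that classifies
    lesions into base damage, single-strand-break and double-strand-break
    (DSB) categories as a function of radiation quality and oxygen
    concentration, microdosimetric helpers (frequency-mean specific energy,
    fluence/LET-weighted yields), a repair-misrepair-fixation (RMF) mapping
    from DSB yields to linear-quadratic survival parameters, and relative
    biological effectiveness (RBE) and oxygen enhancement ratio (OER)
    calculators for DSB induction and cell survival, together with packaged
    reference yield tables and synthetic-data generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
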