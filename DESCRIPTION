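Package: springpotr
Title: Fractional Viscoelastic (Springpot) Analysis of Rheometry Data for
    Tissue-Mimicking Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising soft hydrogels and soft tissue from
    oscillatory shear rheometry. Implements the springpot (fractional-order)
    constitutive element in the frequency and time domains, a
    Grunwald-Letnikov fractional-derivative reference discretisation,
    reduction of amplitude sweeps (linear viscoelastic limits), frequency
    sweeps (inertial cutoff detection and least-squares springpot fits),
    uniaxial compression records (Young modulus, contact-force axial strain
    offset), a linear pre-compression model for the coefficient of
    consistence, concentration power laws, stress-relaxation prediction and
    comparison, and matching of organs to their best agarose phantom
    concentration. Includes a synthetic-data generator emulating the
    statistical structure of rheometer records, a CSV record format, and a
    configurable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
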