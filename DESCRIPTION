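Package: vegfr2akt
Title: Mass-Action Model of VEGFR2 Trafficking and Gab1/Gab2-Dependent Akt
    Activation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic mass-action simulator of VEGF-stimulated VEGFR2
    signaling in endothelial cells, covering receptor trafficking
    (internalization, recycling, degradation), scaffold-protein competition
    between Gab1 and Gab2 for PI3K and Shp2, and downstream Akt activation
    through the PIP3/PDK1/PP2A cascade. Includes scripted in-silico
    experiments (siRNA knockdowns, degradation-rate scans, concentration
    -ratio scans, ligand/receptor titrations), multi-start bounded nonlinear
    least-squares estimation of the six trafficking rate constants against
    max-normalized densitometry time courses, a from-scratch extended
    Fourier Amplitude Sensitivity Test (eFAST) with dummy-parameter noise
    floor, a synthetic western-blot data generator, and SBML Level 3 export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    xml2,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
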