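Package: pulsefate
Title: Single-Cell Fate, Clonal Colour and DNA-Damage Focus Quantification
    After Pulsed Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for single-cell studies of cell
    cycle-dependent responses to pulsed platinum chemotherapy in lung
    adenocarcinoma cultures. Implements RGB (LeGO-style) lentiviral clonal
    colour analysis (rolling-ball background subtraction, regional-maxima cell
    detection, 512-colour quantisation, top-64 reduction and >0.1% clone
    calling with diversity summaries), FUCCI cell-cycle phase calling and a
    single-cell fate ontology (proliferative, single division, G2-exit, G1
    arrest before/after mitosis, death before/after mitosis, S/G2 arrest),
    53BP1/PCNA focus detection with S-phase sub-staging, and control-calibrated
    stable/enlarged size gating. A phase-structured synthetic-data engine
    generates clonal colour populations and images, FUCCI intensity tracks
    with known fates, population phase dynamics and focus kinetics, so every
    analysis stage is testable against ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
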