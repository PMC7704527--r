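Package: qsarlab
Title: QSAR Model Building, Validation and Drug-Likeness Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for quantitative structure-activity relationship
    (QSAR) modelling of small-molecule inhibitor series: IC50 to pIC50
    conversion, descriptor-matrix pretreatment (constant and collinear
    column removal), Kennard-Stone calibration/validation splitting,
    genetic function approximation (GFA) search over descriptor subsets
    scored by Friedman's lack-of-fit, internal validation (R2, adjusted
    R2, standard error of estimate, leave-one-out Q2), external
    validation (predictive R2 about the training mean), regression
    diagnostics (variance inflation factors, descriptor mean effects,
    correlation matrices), leverage-based applicability-domain analysis
    (Williams plot), and drug-likeness screening (Lipinski rule of five
    and bioavailability-radar property ranges).  Ships transcriptions of
    a published anti-proliferative imidazolone series together with the
    published model equations, and a seeded synthetic-data generator
    with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
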