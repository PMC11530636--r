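Package: aerodose
Title: Subject-Specific Radioactive Aerosol Deposition in Parametrized Airway Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale workflow for subject-specific deposition of radioactive
    aerosols in the human respiratory tract: synthetic parametrized bifurcating
    airway trees with morphometric measurement and STL/JSON geometry exchange,
    cohort feature ranking and kernelized k-means phenotype clustering,
    reduced-order airflow (breathing waveform, conductance-based flow splitting,
    laminar velocity profiles, transitional-turbulence inlet boundary
    conditions), Lagrangian particle tracking with Schiller-Naumann drag,
    gravity and Brownian motion under stick-on-contact walls, number- and
    mass-based deposition fraction metrics with lobar splits and impaction
    parameter curves, an NPARC-style grid-convergence toolkit, and batched
    Monte-Carlo point-source deck generation for iodine-131 internal dosimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    randomForest,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
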