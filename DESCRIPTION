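Package: MalonylSensor
Title: Dynamic Modeling and Identification of a Whole-Cell Malonyl-CoA
    Biosensor
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing transcription-factor biosensors from
    microplate kinetic screens, built around a FapR-based malonyl-CoA sensor
    in Escherichia coli. Provides a mechanistic simulator of the biosensor
    cascade (metabolite balance, repressor binding, reporter expression)
    driven by logistic growth, a family of approximate linear filter models
    (one zero, one to three poles) linking biomass to fluorescence, bilinear
    (Tustin) discretization with ARX least-squares identification of gain
    and time constants, and plate-level response analyses: growth-phase
    anchored readouts, dose-response curves, parameter-induction
    correlation, substrate-effect testing and replicate reproducibility.
    Includes a seeded synthetic plate generator emulating 96-well
    OD600/fluorescence kinetic runs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    signal,
    knitr
Config/testthat/edition: 3
biocViews: Software, SystemsBiology, TimeCourse, CellBasedAssays
RoxygenNote: 7.3.3
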