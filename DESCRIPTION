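Package: slnopt
Title: Box-Behnken Design and Response-Surface Optimization of Solid Lipid
    Nanoparticle Formulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for statistically optimizing nanoparticle formulations:
    Box-Behnken experimental designs with replicated center points, reduced
    quadratic response-surface models fit by ordinary least squares in coded
    units with full ANOVA (lack-of-fit, PRESS-based predicted R-squared,
    adequate precision), Derringer-Suich multi-response desirability
    optimization with prediction-interval validation, drug-release kinetic
    model fitting and selection (zero-order, first-order, Higuchi,
    Korsmeyer-Peppas, Hixson-Crowell) by AIC and the model selection
    criterion, and formulation/bioassay arithmetic (encapsulation efficiency,
    drug loading, cumulative release with sampling-replacement correction,
    percent inhibition).  Includes seeded synthetic-data generators so the
    whole pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
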