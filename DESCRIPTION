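Package: ferrokin
Title: Whole-Body Iron Kinetics in the Mouse with Hepcidin Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental ordinary-differential-equation model of whole-body
    iron distribution in the mouse, with an explicit radioactive-tracer (59Fe)
    species set, hepcidin-inhibited ferroportin export, transferrin binding
    kinetics in plasma, and erythroid iron cycling. Provides simulation
    protocols (quasi-steady-state lead-in, tracer injection, diet switching,
    chronic-disease hepcidin elevation), constrained least-squares parameter
    estimation by a stochastic-ranking evolution strategy with Hooke-Jeeves
    refinement, transition-time analysis for model selection, a synthetic
    tracer-data generator for calibration testing, and readers/writers for
    tracer datasets (CSV), parameter sets (JSON), protocol configs (YAML) and
    SBML model export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
NeedsCompilation: yes
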