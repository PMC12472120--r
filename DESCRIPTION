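Package: sbmlode
Title: Compile SBML Models to Executable Ordinary Differential Equations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses Systems Biology Markup Language (SBML) Level 2 and
    Level 3 core documents, including embedded MathML formulas, and
    compiles reaction networks, rules, events and function definitions
    into executable ordinary differential equation (ODE) systems.
    Provides an event-aware adaptive integrator built on deSolve, a
    renderer emitting readable declarative equation text and a
    machine-consumable compiled-model JSON document, a bipartite
    species-reaction graph exporter, a test-suite style validation
    harness that compares simulated trajectories against expected
    results under tolerance rules, and a generator of small SBML
    fixture models with closed-form or fixed-step reference solutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
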