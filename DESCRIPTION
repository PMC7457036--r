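Package: corosim
Title: Closed-Loop Simulation of Coronary Perfusion Coupled with Systemic
    Circulation and Ventricular Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter simulator of the left heart and systemic
    circulation coupled bidirectionally with nonlinear coronary arterial
    networks of the left anterior descending (LAD) and left circumflex (LCX)
    territories. The left ventricle is modelled as two time-varying-elastance
    compartments whose activation can be delayed to represent mechanical
    dyssynchrony; each coronary tree is an order-structured network of
    nonlinear three-element Windkessel vessels compressed by an
    intramyocardial pressure decomposed into cavity-induced, elastance and
    shortening-induced components. Includes synthetic coronary tree
    generation, automated calibration to per-animal hemodynamic targets, a
    flow-dependent contractility feedback for ischemia studies, and scenario
    drivers for control, dyssynchrony and dyssynchrony-with-ischemia
    simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
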