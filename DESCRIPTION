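Package: aerophylo
Title: Static Stability and Control Effectiveness of Gliding Animals Mapped
    onto Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a comparative aerodynamics
    pipeline: six-axis wind-tunnel force/torque records for animal models are
    rotated into the tunnel frame, translated to the center of mass, reduced
    to nondimensional pitching/rolling/yawing moment coefficients, and turned
    into static-stability derivatives (dC/dalpha with 75% confidence
    intervals) and control-effectiveness derivatives (dC/ddelta) at low and
    high angle of attack. Derivatives are discretized into a taxa-by-20
    character matrix (stable/marginal/unstable; effective/ineffective) and
    mapped onto a rooted phylogeny by unordered (Sankoff) parsimony with full
    most-parsimonious-reconstruction state sets. A synthetic virtual
    wind-tunnel generator with analytic ground-truth coefficient curves makes
    every stage testable end to end without physical measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
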