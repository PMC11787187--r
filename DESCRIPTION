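Package: amynet
Title: Nucleation-Aggregation-Clearance Models of Amyloid-Beta Dynamics on Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analytical tools for the chemical kinetics of
    amyloid-beta aggregation, from closed in vitro nucleation-elongation-
    secondary-nucleation master equations to an in vivo single-region model
    with constant monomer supply, mass-saturated secondary nucleation and
    size-dependent clearance, a dynamic clearance-damage (aging) extension,
    and brain-scale transport of aggregates on a weighted connectome through
    the graph Laplacian. Includes closed-form fixed points, equilibrium size
    distributions, critical-clearance (transcritical bifurcation) formulas,
    and a therapeutic layer: secondary-nucleation inhibition, antibody-
    enhanced clearance, periodic dosing profiles, cycle-averaged toxic mass,
    and dosing-regimen optimization under an integrated-dose budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
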