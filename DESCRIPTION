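Package: stackpol
Title: Single-Molecule Force-Clamp Kinetics and Nicked-Duplex Base-Stacking Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for quantifying DNA base-stacking polarity effects.
    One arm turns centrifuge-force-microscope bead movies (or per-tether
    dissociation-time tables) into survival curves, single-exponential off-rates,
    centrifugal forces, and base-stacking free energies with propagated
    uncertainty via an Arrhenius off-rate ratio. The other arm projects
    nicked-duplex trajectory frames onto a two-component (rho, theta) coordinate
    system for the two nick-interface nucleotides and summarizes the resulting
    series as temperature ladders, polar densities, stacked-state occupancies,
    and Gaussian-mixture bimodality reports. Seeded synthetic-data generators
    (exponential dissociation with censoring, bead image stacks, two-state
    stacked/unstacked interface trajectories on an idealized B-form geometry)
    make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    mclust,
    jsonlite,
    yaml,
    tiff,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
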