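Package: zebravis
Title: Vision-Based Stochastic Simulation of Zebrafish Collective Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of zebrafish (Danio rerio) swimming in a
    bounded square arena, optionally containing floating "spots of interest".
    Agents perceive congeners and spots as solid angles captured in a 270
    degree spherical visual field (computed from spherical polygons via
    L'Huilier's theorem), convert percepts into a normalized von Mises
    mixture over candidate headings, and draw each heading by inverse
    transform sampling on a numerically integrated CDF. The package also
    provides the companion trajectory statistics (three-point instantaneous
    speed, turning angles, freezing filter, occupancy grids, pairwise
    distances), a least-squares calibration protocol for the behavioural
    parameters (von Mises concentration fitting and grid search against
    reference summary statistics), and a synthetic-reference trajectory
    generator so the full analysis pipeline can be exercised without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
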