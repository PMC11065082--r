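Package: ringrecal
Title: Ring Attractor Networks with Path-Integration Gain Recalibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Firing-rate simulation and analysis of continuous bump attractor
    networks on a ring, focused on how visual landmarks recalibrate the
    path-integration gain of the network. Provides the full three-ring
    firing-rate model (central ring with local-excitation/global-inhibition
    recurrence, clockwise and counter-clockwise rotation rings, velocity
    neurons, visual drive), a reduced one-dimensional model of the activity
    bump location with a spatially distributed integration gain computed from
    network structure, adaptive gain-update rules with numerical checks of
    the necessary and sufficient sign conditions for recalibration, and a
    modified plastic ring attractor that recalibrates its gain through an
    explicit rate code of positional error combined with Hebbian plasticity.
    Includes generators for synthetic velocity profiles and landmark
    protocols, trajectory input/output, and reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
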