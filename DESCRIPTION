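Package: eqsim
Title: Hebbian Network Simulation of Stimulus Equivalence Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation of stimulus equivalence classes in a
    localist Hebbian network with a coactivation threshold, self-adapting
    weight modulation and spreading activation. Implements matching-to-sample
    trial mechanics with lateral inhibition between comparison units, staged
    training protocols with mastery criteria, and analysis of trained and
    derived (transitive) relatedness by nodal distance. Ships canonical
    replication protocols for classic equivalence studies, including a
    learning-disability parameter variant and an equal-trial-frequency
    control for nodal distance effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
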