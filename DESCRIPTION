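Package: patrolnet
Title: Simulating the Spread of Patrol Knowledge Through Hunting-Community
    Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of how first-hand knowledge of
    conservation law-enforcement patrols diffuses through the social network
    of a hunting community. Generates small communities whose degree
    distributions are lightly, moderately or highly skewed towards the
    star-graph extreme, seeds knowledge into the least- (or best-) connected
    individuals in proportion to patrol effort, and propagates it under a
    listening-probability/listening-threshold contagion rule over discrete
    time-steps. Summarises information flow as the area under the cumulative
    informed-count curve (AUC), runs full factorial simulation experiments
    over community structure, threshold, listening probability and patrol
    effort, and fits per-stratum linear regressions of AUC with sign and
    significance coding. Includes an exact state-space enumeration oracle for
    validating the stochastic dynamics on small graphs, lossless edge-list
    and GraphML network I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
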