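Package: cophycollapse
Title: Linear-Time Greedy Cophylogeny Reconstruction by Cherry Collapse
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Event-based reconciliation of host and parasite phylogenies
    (tanglegrams) under a fixed host node ordering.  Implements a greedy
    linear-time cherry-collapse reconstruction with local pattern detection
    (codivergence, duplication, host switch, loss and four two-event hybrid
    patterns), a loss-minimising post-processing step that relocates host
    switch take-off and landing edges using level-ancestor queries, a genetic
    algorithm over the space of valid internal node orderings, exact
    dynamic-programming and classical reconciliation baselines for small
    instances, and a Yule-process tanglegram simulator.  All reported
    mappings are guaranteed time-consistent (biologically feasible).
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
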