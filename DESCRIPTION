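Package: reconscape
Title: Pareto-Optimal Duplication-Transfer-Loss Reconciliation and Event
    Cost Space Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cophylogenetic and gene-tree/species-tree reconciliation under
    the duplication-transfer-loss (DTL) event model without committing to a
    single set of event costs.  Computes the complete set of Pareto-optimal
    event count vectors by dynamic programming over a tanglegram, counts the
    maximum-parsimony reconciliations achieving each vector, tracks the
    events common to all of them, partitions a user-supplied
    (transfer cost, loss cost) box into equivalence regions with exact
    rational geometry, summarises event consensus support by region or area
    fraction, and runs permutation significance tests of reconciliation cost
    across the cost space.  Includes a worked three-leaf instance, a
    cophylogeny simulator for property testing, and command-line front ends
    for the cost-space, event-consensus and significance analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
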