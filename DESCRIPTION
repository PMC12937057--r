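Package: crnminer
Title: Reactive Pattern Mining and Enrichment Testing for Chemical
    Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Represents per-simulation chemical reaction networks as
    node-injective directed hypergraphs, mines reactive patterns that
    recur across independent exploratory simulations by reduction to
    frequent (closed) itemset mining, and flags patterns statistically
    associated with a binary simulation condition using Fisher's exact
    test with Tarone's correction for family-wise error rate control,
    reporting odds ratios with confidence intervals. Also provides
    Eyring transition-state-theory rate constants from free-energy
    barriers, the Gaussian-accelerated hyperdynamics bias-potential
    formulas on analytic model surfaces with a Langevin demonstration,
    a synthetic reaction-event generator with known ground truth, and
    JSON-Lines/CSV/GraphML input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
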