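Package: fluxcost
Title: Gene-Loss and Function-Loss Costs from Flux Balance Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based estimation of metabolic gene dispensability.
    Computes the classical gene-loss cost of a gene deletion (flux balance
    analysis knockout through the boolean gene-protein-reaction mapping) and
    the function-loss cost, which sums the single-reaction removal costs of
    every reaction a gene participates in, treating isoenzymes as
    non-redundant. Includes minimal-media enumeration over carbon and
    nitrogen sources, correlation of cost metrics with rank-averaged
    evolutionary rates (dN/dS), and prediction of pairwise epistasis under
    redundant and non-redundant isoenzyme semantics, scored against
    experimental genetic-interaction tables. Reads SBML Level 3 (FBC) and
    COBRA-style JSON models; ships deterministic toy-model generators so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
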