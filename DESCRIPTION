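Package: tmea
Title: Thermodynamically Motivated Enrichment Analysis via Surprisal Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surprisal analysis of entity-by-sample log-abundance matrices by
    singular value decomposition, yielding a baseline state, constraint
    weights, time-dependent constraint potentials and free-energy landscapes;
    a directional weight-sum Monte Carlo enrichment test over functionally
    annotated sets (MapMan or GMT) with empirical p-values and
    Benjamini-Hochberg correction; a one-sided hypergeometric
    overrepresentation baseline; weight-ratio versus count-ratio diagnostics
    of the information content of constraint weights; and a synthetic-data
    generator with planted enrichment archetypes for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
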