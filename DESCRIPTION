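Package: netpharm
Title: Network Pharmacology of Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systems-pharmacology analysis of multi-herb formulas: network-based
    drug-target prediction by tripartite substructure-drug-target resource
    diffusion, global bipartite drug-target network statistics and overlap
    analysis, Fisher's-exact compound-disease prioritization with
    Benjamini-Hochberg correction, a four-step active-ingredient screen
    (main-component membership, Lipinski Rule of Five, HIA/BBB gates,
    enrichment significance), a synthetic benchmark generator with planted
    actives, and an end-to-end pipeline with a reproducible run manifest.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
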