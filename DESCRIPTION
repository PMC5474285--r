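Package: herbnet
Title: Network Pharmacology of Herbal Compound-Target Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable network-pharmacology pipeline for evaluating a
    multi-compound herbal preparation against a disease: ADME threshold
    screening of candidate compounds (oral bioavailability, Caco-2
    permeability, Tanimoto drug-likeness) with a literature-rescue list,
    merging of compound-target interaction tables from multiple databases,
    bipartite compound-target and target-pathway network construction with
    degree and normalized betweenness centrality, hypergeometric
    over-representation analysis with Benjamini-Hochberg correction,
    tissue-expression organ localization by above-average calls over an
    immune organ panel, and moderated-t differential-expression comparison
    with target-set intersection. Ships the published compound and target
    tables of Pulsatillae Radix versus Crohn's disease as worked fixtures,
    plus seeded synthetic-data generators with recorded ground truth so
    every stage is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
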