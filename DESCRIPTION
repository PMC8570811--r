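Package: chemesh
Title: Literature Association Mining Between Chemical Entities and MeSH Concepts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an in-memory knowledge graph linking scientific articles,
    chemical compounds, chemical classes and MeSH descriptors, propagates
    article annotations to ancestor concepts under the true-path rule, and
    tests every chemical-entity/descriptor pair for literature
    over-representation with a right-tailed Fisher exact test and
    Benjamini-Hochberg control. Significant associations receive a fragility
    index derived from Jeffreys binomial intervals and a TF-IDF-style MeSH
    profile of their supporting corpus, and can be exported as skos:related
    triples in Turtle alongside full statistics tables. A seeded synthetic
    graph generator with planted enrichments supports end-to-end recovery
    benchmarking, and a command-line interface drives the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
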