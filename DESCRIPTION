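Package: pcoskg
Title: Subtype Markers and Causal Knowledge Graphs for PCOS Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain from a three-group (normal, normoandrogenic PCOS,
    hyperandrogenic PCOS) granulosa-cell expression matrix and a literature
    term-incidence corpus to subtype-specific marker genes, a causal
    knowledge graph terminating at female infertility, and subtype-exclusive
    drug lists. Includes differential and subtype-specific gene calling,
    annotation/PPI/co-occurrence marker cascades, a rank-based random-set
    sample classifier, a dual-quantile-discretization association-rule
    method on expression data, literature co-occurrence rules with Apriori
    chaining, knowledge-graph assembly and pruning, drug-gene interaction
    screening, and a synthetic-data generator with planted ground truth so
    the whole chain is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
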