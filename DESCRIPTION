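Package: goclust
Title: Multi-List Gene Ontology Enrichment and Semantic-Similarity Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline functional mining of multi-comparison gene lists with the
    Gene Ontology. Parses OBO 1.2 ontologies and GAF 2.x (or two-column TSV)
    annotations, propagates annotations along the graph (true-path rule), runs
    one-sided Fisher over-representation tests per interest list with the
    classic or topology-aware elim algorithm, merges per-list results, computes
    information-content (Resnik, Lin, Rel, Jiang) and graph-based (Wang)
    semantic similarities between enriched terms and best-match-average (and
    max/avg/rcmax) similarities between term sets, clusters terms with Ward
    (ward.D2) linkage cut statically or dynamically, names clusters by their
    deepest common ancestor, and exports dendrogram, heatmap, MDS, barchart and
    upset data products with a structured run log. A seeded fixture generator
    produces synthetic ontologies, annotations and study gene lists with
    planted enrichment signal so the whole pipeline is testable without any
    database access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
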