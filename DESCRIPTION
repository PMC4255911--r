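Package: kbmine
Title: Mining Tools for Semantically Integrated Biomedical Knowledge Bases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for mining multi-ontology biomedical knowledge networks.
    Builds merged concept graphs from OBO flat files and relation/mapping
    tables; represents model and clinical parameters as combinatorial
    semantic descriptors (concept sets drawn from orthogonal ontologies) and
    scores descriptor similarity by ontological inference, where concepts
    reachable in few relation steps contribute with diminishing weight;
    extracts lowest-penalty paths from typed association networks under
    user-defined per-edge-class penalties and re-ranks result nodes by
    quality annotations; and groups pathway gene sets by Jaccard overlap at a
    permutation-estimated false discovery rate threshold. Includes seeded
    synthetic-fixture generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
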