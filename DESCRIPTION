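Package: idgba
Title: Information-Distance Guilt-by-Association Subgraph Extension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seed-set expansion in weighted networks by information distance.
    Edge transitions are encoded as self-information (bits) of a random-walk
    step; shortest paths in this information space give node-to-node distances,
    and an equal-length-encoding null model log2(|V|) supplies an automatic,
    data-driven cutoff for the ranked extension of a seed subgraph. Includes
    random-walk-with-restart and personalized-PageRank baselines, an NDCG
    hold-out evaluation protocol, construction of differential co-expression
    graphs from case/control expression matrices with spectral cluster
    selection, disease-disease graphs from gene association scores, and
    synthetic generators with planted structure for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
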