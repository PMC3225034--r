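Package: trsnet
Title: Discovery of Transcription-Regulating Signaling Pathways and Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies signaling pathways whose member genes are
    transcriptionally perturbed in an expression experiment (TRS Pathways)
    and chains them into TRS Networks through transcription-factor to
    target-gene edges. Builds a directed omics network from protein-protein
    and protein-DNA interaction edge lists, filters edges by subcellular
    localization order and by a logistic-regression interaction reliability
    model, scores candidate paths against Monte-Carlo backgrounds so that
    random gene sets score with mean zero and unit standard deviation,
    enumerates top-scoring start-to-end paths with a k-best search,
    grows cross-talk networks by a queue-based expansion over
    transcription-factor targets, and assesses significance by expression
    permutation. Includes a synthetic-data generator with planted pathways
    for benchmarking, a D2D baseline, and Fisher exact overlap tests
    against reference pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
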