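Package: semlink
Title: Semantic-Evidence Graph Encoding and Tucker Decomposition for
    Knowledge-Graph Link Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Link prediction and completion for multi-relational knowledge
    graphs. Entities and relations are embedded by a graph neural network that
    aggregates three levels of semantic evidence (relation-level, entity-level,
    and triple-level neighbour attention) and scored by a Tucker core-tensor
    decoder with an optional nonlinearity. Includes 1-N binary cross-entropy
    training with Adam and early stopping, the filtered ranking protocol
    (MRR, MR, Hits at k), threshold-based graph completion, and a seeded
    synthetic knowledge-graph generator with structured motifs for
    benchmarking. Triple files use the tab-separated train/valid/test dialect
    of the standard link-prediction benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
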