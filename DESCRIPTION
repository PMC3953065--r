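Package: figrank
Title: Listwise Learning-to-Rank for Figures in Full-Text Articles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks the figures of a scientific full-text article by importance
    with a supervised listwise learning-to-rank model.  Articles are parsed
    from a plain JSON schema or JATS-like XML, figures are represented by
    centrality, frequency, topic-model and structural features computed from
    captions and figure-associated text, and a linear scorer is trained by
    gradient descent on a cross-entropy loss over Plackett-Luce top-1 or
    top-2 permutation probabilities.  Includes tie-aware rank-weighted
    evaluation metrics, forward greedy feature selection, a LETOR-format
    reader/writer, and a synthetic corpus generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
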