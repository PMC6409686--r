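Package: pathseeker
Title: Mining Drug-Protein-Side Effect Paths from Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers putative drug-protein(-protein...)-side effect paths from
    biomedical abstracts. Parses MEDLINE/PubMed XML, recognizes drug, protein
    and side-effect mentions by dictionary n-gram matching, extracts directed
    entity-verb-entity relations with rule-based negation, voice and distance
    filters, assembles a typed knowledge graph, enumerates k-protein-depth
    paths (k = 1..3), and ranks them with a hybrid score combining COALS
    corpus similarity, side-effect-local pair frequency and concept-hierarchy
    (Wu-Palmer) similarity. Includes precision-at-k evaluation, baseline
    rankers, and a deterministic synthetic-corpus generator with planted
    ground-truth chains for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
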