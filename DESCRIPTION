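Package: bioevex
Title: Biomedical Event Extraction with Sequential-Pattern Sample Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts GENIA-style biomedical events (trigger plus theme and
    optional cause or second theme) from text annotated in BioNLP-ST standoff
    format.  Training corpora for this task are heavily imbalanced towards
    negative trigger-argument pairs; the package mines frequent sequential
    patterns (PrefixSpan) from the dependency-label paths of annotated event
    pairs and filters candidate pairs by how many mined patterns their path
    contains.  Multi-argument events (Binding, regulation) are extracted as
    triplets directly and integrated with pairwise predictions, and a joint
    score combining letter-trigram sentence similarity with trigger importance
    estimated on the training annotations prunes low-confidence events.  A
    synthetic-corpus generator emulating the nine GENIA event types, nested
    regulation and a configurable class imbalance supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
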