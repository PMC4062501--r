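Package: srlkit
Title: Collective Semantic Role Labeling on Constituency Parse Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constituent-by-constituent semantic role labeling of
    biomedical text in the PropBank style. Implements a resource-saving
    preprocessing stage (a four-rule tree-pruning filter plus association-rule,
    word-list, pattern and parse-path argument-candidate identifiers), a
    log-linear collective labeling model with hard tree- and path-collective
    constraints decoded exactly by branch-and-bound or cutting-plane search,
    1-best MIRA online training, argument-wide and structure-wide CoNLL-style
    evaluation with a resampled t-test protocol, and a seeded generator of
    annotated synthetic corpora shaped like biomedical proposition banks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
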