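Package: biodtm
Title: Dynamic Topic Models for Biomedical Literature with a Restricted
    Bio-Vocabulary
Version: 0.1.0
Authors@R:
    person("biodtm", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A pipeline that turns a time-stamped collection of biomedical
    abstracts (PubMed MEDLINE exports) into a fitted dynamic topic model over
    discrete time slices, with the model vocabulary restricted to a
    user-supplied biomedical dictionary of stemmed unigrams.  Includes a
    MEDLINE tagged-record parser, a Porter stemmer, tf-idf and
    total-frequency vocabulary pruning, variational EM inference for
    smoothly drifting topic-word distributions, per-slice top-word tables
    and topic-strength trajectories, a ThemeRiver stacked-stream SVG
    renderer, and a synthetic-corpus generator with known ground truth for
    end-to-end testing without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
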