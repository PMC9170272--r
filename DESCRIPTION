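Package: lingsync
Title: Session-Level Linguistic Synchrony in Dyadic Conversation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures session-level linguistic synchrony between the two
    speakers of a conversational dyad, with psychotherapy transcripts as the
    motivating use case. Each session is split into speaker-specific
    sub-transcripts, scored on four 0-100 summary variables (analytic
    thinking, clout, authenticity, emotional tone) with a user-supplied
    LIWC-style category dictionary, and the resulting per-dyad profile
    matrix is standardized and clustered with k-means at an elbow-selected
    number of clusters. A session counts as synchronized when its therapist
    and client sub-transcripts fall into the same cluster, yielding per-dyad
    synchrony percentages and the temporal distribution of synchrony across
    the treatment span. Includes a planted-structure simulator for both
    token streams and profile matrices, a bundled three-dyad case-study
    dataset, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
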