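Package: kwtrends
Title: Temporal and Network Trend Analysis of Publication Keywords
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for co-word trend analysis of article metadata. From records
    carrying a publication year and a keyword list, builds an annual
    keyword-frequency matrix, quantifies year-over-year topic drift with the
    weighted Jaccard similarity, segments the timeline into chronological
    research phases, constructs a keyword co-trend network, and clusters it
    with a Markov Cluster (MCL) implementation. Includes a synthetic-corpus
    generator with planted temporal structure (emerging, declining and pulsed
    topic groups, synonym variants, terminology renames) so every stage of the
    pipeline can be validated against a known ground truth, and an adjusted
    Rand index to score cluster recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    stringi,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
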