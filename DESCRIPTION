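Package: enrichsum
Title: Collective Filtering and Comparison of Enrichment Analysis Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes one or more rank-ordered functional enrichment results
    against a GMT annotation collection using a subset-coverage principle: a
    term is discarded when a more significant term annotates at least the same
    genes, and the more significant term becomes its representative. Multiple
    result lists are merged and filtered collectively, enabling comparison of
    enrichment analyses across conditions. Outputs comparison-ready summary
    tables (TSV), a browsable HTML report, a rank-quartile heatmap and a
    represented-term barplot. Includes a synthetic-data module that generates
    hierarchical (parent-superset) annotation collections, artificial query
    gene lists and hypergeometric over-representation analysis, so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
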