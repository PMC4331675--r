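Package: ppipath
Title: Integrate, Search and Visualize Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building personalized protein-protein interaction (PPI)
    networks from heterogeneous database downloads. Parses PINA- and
    iRefIndex-style tab-delimited interaction tables and STRING links/alias
    files, canonicalizes protein identifiers to primary UniProtKB accessions
    via a gene-name mapping table, merges sources into one evidence-annotated
    interaction set with per-database overlap accounting, and searches the
    resulting weighted graph. Edge costs follow a confidence-based model
    (curated evidence costs 1; STRING edges cost max(1, log100(1000 - score)))
    and all cost-minimal or step-minimal interaction paths between proteins
    are enumerated from a tie-aware predecessor DAG. Query-centric subnetwork
    views (neighborhoods, multi-protein views with mediator proteins, path
    views) can be exported as self-contained HTML pages and as a reversible
    one-line text encoding for sharing. A seeded synthetic-fixture generator
    produces all supported input dialects with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
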