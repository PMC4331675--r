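# ppipath

Build, search, and share personalized protein–protein interaction (PPI)
networks from heterogeneous database downloads.

Public PPI resources ship their data in incompatible dialects: curated
indexes such as PINA and iRefIndex distribute MITAB-like tab-delimited
tables carrying the PubMed IDs that support each interaction, while STRING
distributes `protein1 protein2 combined_score` links files (with a separate
alias file for its internal identifiers) in which many associations are
computationally predicted. `ppipath` is for molecular and systems biologists
who want to fold these sources — plus their own privately collected
interactions — into one evidence-annotated network, ask *how two proteins
can be connected*, and publish the answer as a self-contained web page.

## What it does

- **Parse** PINA-style and iRefIndex-style interaction tables and STRING
  links/alias files (default confidence threshold 700), tolerating the dirt
  of bulk downloads.
- **Canonicalize** every gene name, synonym, or secondary accession to a
  primary UniProtKB accession; records that cannot be mapped are discarded
  and counted.
- **Combine** all sources into one standardized TSV (one row per unordered
  protein pair, supporting databases and PubMed IDs merged), with a
  per-database overlap/distinct census for both proteins and interactions.
- **Search** the weighted interaction graph. Each edge has a *cost* ≥ 1:
  curated evidence costs exactly 1, and a STRING association with combined
  score *s* costs

  &nbsp;&nbsp;&nbsp;&nbsp;cost(*s*) = max(1, log₁₀₀(1000 − *s*))

  so a score of 900 costs exactly 1 and lower-confidence links are
  penalized. An edge supported by several sources takes the minimum cost;
  users can override any cost in the TSV. `shortest_paths()` enumerates
  **all** cost-minimal paths between two proteins (or all step-minimal
  paths with `by_step = TRUE`), and `single_source()` screens one protein
  against the whole network.
- **Visualize and share**: neighborhood views (display capped at a random
  sample of 100 interactions for hubs, full evidence table retained),
  multi-protein views with mediator (scaffold) proteins that touch at least
  two main proteins, path views, self-contained HTML pages, ggplot2
  `autoplot()` methods, and a reversible one-line text encoding of any
  graph for sharing by email.
- **Simulate**: a seeded generator (`gen_random_ppi()`, `gen_path_graph()`,
  `gen_hub()`) writes all of the above input dialects for synthetic
  networks with known ground truth, so the entire pipeline is testable
  offline.

## Worked example

```r
library(ppipath)

# synthetic stand-in for real downloads: writes PINA/iRefIndex/STRING files,
# a STRING alias file and a UniProtKB-style mapping file
bundle <- gen_random_ppi(n_proteins = 50, n_edges = 120, seed = 42)

res <- run_fixture_pipeline(bundle)   # parse -> map -> combine -> graph
res$graph
#> <ppi_graph> 50 proteins, 120 interactions
#>   edge cost: min 1, max 1.167; 0 cost override(s)

res$overlaps
#> Overlapping and distinct proteins per database:
#>           PINA STRING iRefIndex distinct
#> PINA        50     44        48        0
#> STRING      44     44        42        0
#> iRefIndex   48     42        48        0
#>
#> Overlapping and distinct interactions per database:
#>           PINA STRING iRefIndex distinct
#> PINA        79     23        24       38
#> STRING      23     43        14       12
#> iRefIndex   24     14        53       21
```

The diagonal holds each database's own count of valid proteins (or
interactions); off-diagonal cells are pairwise intersections; `distinct` is
what only that database contributes. Here 79 interactions came from the
PINA-style file, 23 of which are also in the STRING-style file, and 38 of
which no other source reports.

```r
ps <- shortest_paths(res$graph, "GN0001", "GN0050", mapping = res$mapping)
ps
#> <ppi_path_set> P00001 -> P00050: 4 shortest path(s), total cost 3
#>    P00001 - P00026 - P00016 - P00050
#>    P00001 - P00034 - P00029 - P00050
#>    P00001 - P00041 - P00029 - P00050
#>    P00001 - P00043 - P00015 - P00050
```

Gene names were resolved through the mapping table; all four routes cost 3
(three curated, cost-1 steps each), and every tie is reported, not just
one winner. `tidy(ps)` turns the result into a tibble; `autoplot(ps)`
draws it; and

```r
render_html(as_view_document(path_view(res$graph, ps), mapping = res$mapping),
            "paths.html")
```

writes a single self-contained page with a force-directed graph and the
per-edge evidence table (databases, PubMed IDs, STRING scores).

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "ppipath.R", package = "ppipath")` with subcommands
`fixtures`, `format`, `mapping`, `combine`, `path`, `view`, `export`.

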