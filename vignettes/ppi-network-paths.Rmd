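---
title: "Methods: integrating PPI databases and enumerating shortest interaction paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating PPI databases and enumerating shortest interaction paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppipath)
```

## The problem

Protein–protein interaction (PPI) evidence is scattered across databases
with different identifier conventions, file dialects, and levels of trust:
curated indexes (PINA-style, iRefIndex-style downloads) list experimentally
supported interactions with their PubMed provenance, while STRING-style
links files mix known and *predicted* associations, graded by an integer
combined score in 0–999. A biologist who wants to reason about how two
proteins might communicate needs these sources folded into one graph in
which (a) the same protein is one node regardless of how each source names
it, and (b) an edge's weight reflects how trustworthy its evidence is.
`ppipath` implements that integration and the search on top of it.

## Identifier canonicalization

All nodes are primary UniProtKB accessions. The mapping table
(`build_mapping()`) reads a five-column TSV (accession, reviewed flag,
gene name, synonyms, secondary accessions) and resolves any of those
tokens, case-insensitively, to the primary accession. Two rules make the
table deterministic regardless of input order:

1. when a reviewed (Swiss-Prot) and an unreviewed (TrEMBL) entry claim the
   same name, the reviewed entry wins — manual annotation outranks
   automatic annotation;
2. remaining ties break lexicographically by accession.

A primary accession always resolves to itself, even if another entry lists
it as a secondary accession. Lookups that fail return `NA` rather than
erroring (`resolve_protein()`), because the pipeline's policy for
unmappable proteins is *discard and count*, not abort: bulk downloads
always contain a tail of unmappable identifiers, and losing them must be
visible (the discard count) but not fatal.

## Parsing and the standardized table

The parsers are header-first: interactor columns default to the first two
columns and the PubMed column is located by a header name matching
`pubmed`/`pmid`/`publication`, falling back to a positional default
(column 9 for PINA-style files, 7 for iRefIndex-style) that is exposed as
an argument because MITAB-like layouts vary between snapshots. Known
identifier prefixes (`uniprotkb:`, `refseq:`, `entrezgene/locuslink:`) are
stripped; unknown prefixes are left for the mapping stage. Malformed lines
are skipped and counted. STRING rows are filtered at `score_threshold`
(default **700**, the conventional high-confidence cutoff; tunable per
run) and translated through the alias file, dropping and counting rows
with no alias.

All sources converge on one standardized TSV (`accA, accB, sources,
pmids, string_score, cost`): one row per unordered pair (lexicographic
order, so (A,B) ≡ (B,A)), `;`-joined sorted source labels, `;`-joined
ascending PubMed IDs, and an optional user-edited `cost` column. The file
is deliberately plain (UTF-8, Unix newlines) so users can edit costs in a
text editor; `read_standard()`/`write_standard()` are an exact identity,
which the suite property-tests. Self-pairs are allowed — curated databases
do list homodimers — and they are counted as interactions in the overlap
census, though the path search ignores self-loops (they can never shorten
a path when all costs are ≥ 1).

## Combining sources and the overlap census

`combine_ppi()` merges per-source canonical sets: supporting databases are
unioned, PubMed IDs unioned, and the STRING score carried when STRING
supports the pair. The census mirrors the usual integration report: a
matrix whose diagonal is each database's own count and whose off-diagonal
cells are pairwise intersections, plus a distinct count (items present in
exactly one database), computed separately for proteins and for
interaction pairs. A protein counts as *valid* for a database when it
appears in at least one kept interaction of that database; this is a
design choice (an isolated identifier never occurs in an interaction
download) and is stated here because other conventions exist. Privately
collected interactions participate as an extra set under any user-chosen
source label and behave like curated evidence.

## The edge-cost model

Costs quantify how unfavorable it is to traverse an edge and are always
≥ 1:

- curated evidence (PINA-style, iRefIndex-style, private sources): cost 1;
- STRING evidence with combined score $s \in (0, 1000)$:
  $\mathrm{cost}(s) = \max\!\bigl(1,\ \log_{100}(1000 - s)\bigr)$.

The formula maps score 900 to exactly 1 ($\log_{100} 100$), score 700 to
$\log_{100} 300 \approx 1.2386$, and clamps at 1 from score 900 upward
(score 999 gives $\log_{100} 1 = 0$, clamped). When an edge carries both
curated and STRING evidence the package takes the **minimum** of the
per-source costs. This is a deliberate choice where several conventions
are defensible: the most favorable evidence should govern path search, and
it keeps any curated edge at the documented default of 1. A user override
(≥ 1, from the `cost` column) always wins. Scores outside (0, 1000) are
domain errors rather than silent clamps, because they indicate a malformed
input file.

## All-shortest-paths enumeration

`dijkstra_predecessors()` runs Dijkstra's algorithm from the source and
records, for every settled node, *every* predecessor achieving the optimal
distance within an absolute tolerance of `1e-9`. The tolerance exists
because costs are floating-point sums ($\log$ values plus integers); two
routes of equal cost can differ in the last bits depending on summation
order. The selection loop is a vectorized $O(n^2)$ scan rather than a
heap: the networks this package targets (up to a few thousand nodes) make
the simpler, allocation-free form faster in practice and easier to verify.

The resulting predecessor DAG is acyclic under strictly increasing
distance, so backward traversal from a target (`enumerate_paths()`)
multiplies out every tie and yields each distinct shortest path exactly
once. Paths are sorted deterministically — fewer steps first, then
lexicographically by accession sequence — and enumeration is capped
(default **100** paths) with an explicit `truncated` flag, because tie
structure can make path counts exponential; the deterministic sort makes
the truncated prefix reproducible. An unreachable target returns an empty
path set with an `unreachable` flag, never an error, and `source ==
target` returns one zero-length path.

With `by_step = TRUE` every edge is treated as cost 1, so distances are
hop counts and results are minimum-step paths; the suite checks these
against breadth-first depth computed by igraph, and checks cost-mode
enumeration against a brute-force all-simple-paths oracle on small random
graphs (both orthogonal implementations). `single_source()` reuses one
predecessor DAG for all targets, and `write_path_atlas()` shards the
result into one JSON + HTML document per target plus an index, so a
screening run can be hosted statically and browsed without R.

## Subnetwork views

Three view constructors share the same vocabulary: *main* nodes show all
their mutual interactions; *input leaf* nodes (query proteins explicitly
demoted by the `main` argument) show only their interactions with main
nodes; *mediator* nodes are non-query proteins interacting with **at least
two** main (or on-path) proteins, included because interactions are often
bridged by scaffolding proteins. Mediators show only their edges to
main/path nodes — mediator–mediator edges are excluded so the periphery
stays readable; this is a documented design choice. `path_view()` computes
mediators against the union of nodes across all enumerated shortest
paths, surfacing near-optimal context around the optimal routes, and keeps
each individual path as highlighting metadata.

Single-protein neighborhoods cap the *displayed* edges at a uniform random
sample of 100 when the protein has more than 100 interactions, while the
evidence table always retains the full set. Sampling is seeded (default
seed 0) so rendered views are reproducible; sampling at exactly 100
interactions does not trigger. Views emit style *classes* (main/leaf,
large/small), not pixel values; concrete colors live in the render
templates so users can restyle without touching the data.

## Export formats

`render_html()` writes a single self-contained page — embedded JSON data
block, inline force-directed layout script, evidence table — so results
work from a local file system, a static web server, or a cloud drive with
no extra assets; rendering is byte-deterministic. The one-line *graph
text* encoding (`serialize_graph_text()`/`parse_graph_text()`) is this
package's own versioned format (`PPIGT1|…`, percent-escaped fields) for
sharing editable graphs through email or messengers: it round-trips
nodes, labels, style classes, edges, and directedness flags exactly, and
parse failures report a character position.

## The synthetic-data generator

`gen_random_ppi()` writes every input dialect for a random network:
each sampled edge joins each source independently with the `source_mix`
probabilities (default PINA 0.5, iRefIndex 0.35, STRING 0.3 — curated
sources dominate, with substantial overlap, as in real integrations; an
edge drawing no source is assigned one proportionally). STRING scores are
uniform on 700–999 by default so every synthetic row survives the default
threshold; curated records carry 1–3 synthetic PubMed IDs from a fixed
range, about 10% of curated records are written twice (reversed, with an
extra PubMed ID) to exercise within-source deduplication, and 5% of
records reference unmappable decoy proteins to exercise the discard rule.
Species prefix `9606.` mimics the real links-file shape. Generation is
fully deterministic under the seed — regeneration is byte-identical — and
each bundle carries its own ground truth (standardized table, graph,
overlap census) computed from the generator's bookkeeping, against which
the parse→map→combine pipeline is required to be *exactly* closed.

What the generator does **not** emulate: realistic degree distributions
(edges are uniform over pairs, real PPI networks are scale-free-ish),
organism-specific topology, inconsistent capitalization or obsolete
accessions beyond the decoy mechanism, and MITAB columns the parsers do
not read. Passing tests therefore demonstrate correctness of the
*mechanics* (parsing, mapping, merging, counting, searching) on networks
of known truth, not robustness to every pathology of real downloads.

`gen_path_graph()` builds layered source-to-sink graphs (complete
bipartite between consecutive layers, all costs 1) whose shortest-path
count is the product of interior layer widths — exact combinatorial ground
truth for the enumerator. First and last layers must have width 1 so the
source and sink are unique. `gen_hub()` builds stars for the display
sampling boundary.

## Problem sizes and numerical choices

The test suite and the acceptance script run on networks of 2–50 proteins
(up to ~120 interactions), 100-fold randomized view sweeps, exhaustive
edge-subset sweeps over 4-node pools, and random 8-node instances for the
brute-force path oracle — sizes at which exhaustive oracles are exact and
the full suite completes in well under a minute. Cost comparisons use
absolute tolerance `1e-9` throughout; equality of tables, files, and text
payloads is asserted byte-exactly, never approximately.

## Known limitations

- Interactions are undirected; directionality exists only as a flag in the
  shareable graph-text format, not in the search.
- No confidence fusion beyond the minimum rule; combining scores across
  sources (e.g. Bayesian integration) is out of scope.
- Only optimal (cost- or step-minimal) paths are enumerated; there is no
  ranking among suboptimal paths beyond the mediator context in views.
- The browser pages use a small self-contained layout script, not a full
  interactive editor; editing workflows run through the reversible text
  encoding instead.
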