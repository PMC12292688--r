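---
title: "netpharm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netpharm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# The problem

Network pharmacology asks which genes are most influential in the
interaction network linking a disease's associated genes with the targets
of drugs used against it. The workflow implemented here is the common
one: aggregate disease genes and compound targets from several curated
sources, intersect them, build a protein–protein interaction (PPI)
network over the shared genes at a confidence threshold, and then
identify "core" genes two complementary ways — by iterated median
filtering on a panel of centralities, and by top-*k* hub ranking — before
asking which biological pathways the gene list over-represents.

Everything runs offline: a synthetic-data module stands in for the live
databases (GeneCards-, DrugBank-, PharmGKB-, PubChem-, STRING- and
KEGG-style inputs), and every stage reads and writes plain-text formats
(TSV, GMT, GraphML, JSON).

# The network model

The PPI network is a simple undirected graph over uppercase gene symbols.
Edges carry a STRING-convention combined confidence score on the 0–1000
integer scale; `build_graph()` keeps an edge when
`combined_score >= round(1000 * threshold)` with both endpoints in the
analysis gene list. The comparison is inclusive — a score of exactly 400
survives the default 0.400 ("medium confidence") threshold, matching the
behavior of the STRING web filter. Topology is unweighted everywhere
downstream; the score is metadata only.

Genes of the list with no surviving interaction are dropped by default
(the default STRING/Cytoscape view); `keep_isolates = TRUE` retains them
with zero centralities, and `lcc_only = TRUE` restricts to the largest
connected component for users who want the classical single-component
analysis.

# Centrality measures

Six measures are computed (`profile_all()`), chosen to match the two
plugin tool chains this workflow is usually run with: the five-measure
filtering panel (degree, betweenness, closeness, eigenvector, LAC) and
the hub-ranking pair (degree, MCC).

* **Degree** — neighbor count.
* **Betweenness** — for node $v$,
  $\sum_{\{s,t\}, s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$ over
  unordered pairs, where $\sigma_{st}$ counts shortest $s$–$t$ paths.
  Reported raw by default; `normalized = TRUE` divides by
  $(n-1)(n-2)/2$. The median filter is invariant to this monotone
  rescaling, so the choice does not affect core extraction.
* **Closeness** — $(k-1)/\sum_u d(v,u)$ with the sum taken inside $v$'s
  connected component of size $k$; singletons score 0. The textbook
  "average distance to all other nodes" is undefined on disconnected
  graphs, and the within-component form is what common tools compute. A
  `harmonic = TRUE` variant (mean of $1/d$, unreachable nodes
  contributing 0) is available as the globally well-defined alternative.
* **Eigenvector** — principal eigenvector of the adjacency matrix, per
  connected component, nonnegative, unit Euclidean norm within each
  component. Computed by *shifted* power iteration on $A + I$: the shift
  leaves eigenvectors unchanged but makes the dominant eigenvalue
  strictly largest in modulus, so the iteration also converges on
  bipartite components (a plain power iteration oscillates on, e.g., a
  star). The start vector is all-ones, making results deterministic;
  convergence is declared when successive normalized iterates differ by
  less than `tol = 1e-10` in max-norm, and failure to converge within
  `max_iter` is an error, never a silent approximation.
* **LAC** (local average connectivity) — the mean degree of $v$'s
  neighbors inside the subgraph induced by those neighbors. This is the
  neighborhood-density measure of the CytoNCA panel; a star center has
  LAC 0, a clique member of $K_n$ has LAC $n-2$.
* **MCC** (maximal clique centrality) —
  $\sum_{C \ni v} (|C|-1)!$ over *maximal* cliques $C$, the CytoHubba
  definition. Maximal cliques are enumerated exactly (Bron–Kerbosch with
  pivoting); a configurable clique-count cap guards against pathological
  dense inputs. When every maximal clique through $v$ is a single edge,
  MCC reduces to the degree.

Ties are preserved exactly — no jitter is ever added — and all measures
are invariant under node relabeling (tested by permutation).

# Core extraction

`extract_core()` implements the iterated median filter: in each round,
compute the panel centralities on the *current* graph, keep the nodes
whose value strictly exceeds the median on **every** panel metric
(conjunction), and take the induced subgraph. Two rounds is the default.
Three choices deserve comment:

* **Recomputation per round.** Centralities and medians are recomputed
  on each surviving subgraph. This is the only reading under which a
  second identical filtering pass narrows the network further, and is
  how the filter is applied in practice with CytoNCA.
* **Strict comparison.** "Higher than the median" is taken literally;
  when a metric is constant across nodes the strict filter empties the
  graph and the error names the offending metric. An
  `comparison = "inclusive"` fallback keeps median ties for such
  degenerate graphs.
* **Median of an even count** is the mean of the two central values.

A worked failure mode: a 6-node path has degrees (1,1,2,2,2,2), median
2, and no node strictly above it — the round (and the extraction, with
the round index) aborts rather than returning an empty network.

# Hub ranking

`rank_hubs()` ranks by degree or MCC on the **full, unfiltered**
network — hub identification deliberately bypasses the median filter,
mirroring the published workflow that ran the two analyses in parallel.
Rows are ordered by score descending with lexicographic tie-breaks for a
deterministic printed order, but tied scores share a *competition rank*
(1, 2, 3, 4, 4, 6, …), the convention of published hub tables. Every node
tied with the *k*-th score is included even when that pushes the table
beyond *k* rows: truncating inside a tie would be irreproducible. The
default consensus of the degree and MCC top-10 lists is their
intersection (conservative); union is available. `hub_subnetwork()`
returns the induced subgraph on the hubs and their first neighbors.

# Over-representation analysis

For a list of $k$ genes inside a background universe of $N$, a pathway
with $K$ background members and overlap $m$ is scored by the exact
upper-tail hypergeometric probability $P(X \ge m)$, and the effect size
is the fold enrichment

$$\mathrm{FE} = \frac{m/k}{K/N},$$

the share of the list inside the pathway over the corresponding
background share. P-values are adjusted by Benjamini–Hochberg across the
**whole tested family** — every pathway with at least one member inside
the background — and only then are rows filtered to overlaps of at least
`min_overlap` (default 2, the smallest overlap published tables
typically print) and sorted by FDR. Testing the full family, rather than
only the reported rows, keeps the FDR meaningful and makes the result
invariant to pathway input order. The background defaults to the union
of all GMT members and can be overridden with an explicit universe file;
pathway members outside the background are discarded before testing.

## Cross-checking published tables

A published ORA table usually prints $(m, K, \mathrm{FE},
\mathrm{FDR})$ but not $k$ or $N$. Since
$\mathrm{FE} = (N/k)\, m/K$, each row implies the single ratio
$r = N/k = \mathrm{FE} \cdot K / m$, and a self-consistent table has one
common $r$. `crosscheck_fold_enrichment()` estimates $r$ for each row
from the *other* rows (leave-one-out median) and predicts that row's
fold enrichment as $r\,m/K$. On the published table shipped in
`extdata/published_enrichment_table.tsv` all ten predictions agree with
the printed one-decimal values within a single rounding unit (±0.2), and
the fitted ratio is ≈ 422.3. The FDR column of such a table is *not*
recomputable without the unstated $k$, $N$ and full test family, so only
the fold-enrichment column is validated. The ratio is used only for this
validation; nothing in the analysis code assumes it.

# The synthetic-data generator

`generate_scenario()` states a small, explicit world:

* **Universe** of `n_bg = 1000` symbols; `n_dis = 120` disease genes
  with lognormal relevance scores (meanlog $\log 8$, sdlog 0.7, rounded
  to 2 dp — heavy-tailed like curated association scores); `n_cmp = 90`
  compound targets of which all but 5 are shared with the disease list,
  so the analysis list (the disease∩compound intersection) has 85 genes.
* **Interaction network** over the analysis list: preferential
  attachment with $m = 2$ edges per arriving node, *seeded with a clique
  on the `n_hubs = 5` planted hubs* and with triangle closure — after a
  preferential first target, the second attaches to a uniformly chosen
  neighbor of the first with probability 0.9. Pure $m=2$ preferential
  attachment produces near-zero clustering, which real PPI modules do
  not show; without the hub clique and triad closure the planted hubs'
  LAC falls below the median and a five-metric conjunctive filter
  removes them, defeating the generator's purpose of planting
  *recoverable* hubs. The rich-club seed plus closure is the minimal
  change that gives hubs the dense neighborhoods ("high link density")
  the hub concept presumes, while keeping the heavy-tailed degree
  distribution.
* **Edge scores**: true edges uniform on 401–999; an equal number of
  decoy non-edges scored 1–399, so the default 0.400 threshold is
  exercised exactly (decoys out, true edges in).
* **Pathways**: 25% of the `n_pathways = 20` pathways are planted
  enriched. A planted pathway of size $s$ (sizes uniform 20–80) draws
  $\max(1, \mathrm{round}(\phi s))$ members from the analysis list and
  the remainder uniformly from the background *excluding* the list;
  non-planted pathways draw uniformly from the full background. Drawing
  the planted remainder from the background-minus-list makes the effect
  size interpretable: setting $\phi$ equal to the list's background
  fraction (85/1000) reproduces a uniform draw exactly, giving a
  calibrated null (median planted fold enrichment ≈ 1), which the test
  suite asserts over 50 seeds. Drawing the remainder from the full
  background would inflate the null fold enrichment to ≈ $2 - \phi$.
* **Determinism**: one integer seed drives everything through a
  save/restore RNG scope; the global random stream is untouched, and
  identical seeds give byte-identical files from `write_scenario()`.

What a green recovery test establishes — and what it does not: the
generator plants hubs as a connected rich-club, so recovery shows the
pipeline finds *that kind* of hub structure; it says nothing about hubs
embedded in sparser, tree-like neighborhoods (which a conjunctive
LAC filter will, by design, discard), about score calibration of real
curated databases, or about biological identity of any gene.

# Pipeline and configuration

`run_pipeline()` chains the stages and writes every intermediate
artifact plus `manifest.json` (input MD5 checksums, parameters,
per-stage node/edge counts, the hub list, and an explicit note that
experimental verification is out of scope). The configuration file is
JSON rather than YAML — no YAML parser is available in the dependency
set, and JSON covers the same structure; unknown keys are rejected by
name, defaults (confidence 0.400, 2 strict rounds over the five-metric
panel, top-10 degree+MCC hubs with intersection consensus, min_overlap
2) are filled in. The disease catalog is always the union of the
supplied disease-side sources (any subset of GeneCards/PharmGKB/PubChem
tables may be configured); when a drug-target table is present the
analysis list is the disease∩compound intersection, otherwise the full
disease catalog — the two entry arms of the standard workflow diagram.
Reruns of the same config are byte-identical.

# Numerical and edge-case choices

* Symbol normalization is uppercase+trim only; no alias mapping service
  is consulted (offline determinism).
* Duplicate symbols or edges collapse keeping the **maximum** score —
  monotone and order-free.
* Hypergeometric tail probabilities use R's exact `phyper`
  (log-space-stable); tests check them against direct
  binomial-coefficient summation.
* BH adjustment is validated against hand-worked step-up cases and its
  monotonicity/clipping properties.
* `fold_enrichment()` is 0 iff the overlap is 0; division guards reject
  nonpositive $k$, $K$, $N$.
* Empty surviving edge sets are a *warning* (a valid empty graph) at
  build time but an *error* at export and ranking time, with the
  confidence threshold named.

# Known limitations

* MCC is exponential-time in the worst case; the clique cap turns
  pathological inputs into a clear error instead of a hang.
* LAC and closeness are quadratic-ish in the implementation; fine for
  the few-hundred-node networks of this workflow, not for proteome-scale
  graphs.
* The published hub table's gene identities and scores depend on
  unversioned live database snapshots and are *not* reproducible
  offline; the table is used only as a schema and rank-tie-format
  fixture.
* Only over-representation analysis is implemented — no ranked (GSEA)
  or topology-aware pathway statistics.
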