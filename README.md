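# netpharm

An offline, reproducible network-pharmacology pipeline in R, for
bioinformaticians who want the standard disease/drug target workflow —
multi-source target aggregation, PPI network construction, centrality
analysis, hub-gene identification, and pathway over-representation — as
tested library code rather than a sequence of point-and-click tool runs.

## What it computes

1. **Gene catalog** — read GeneCards-, DrugBank-, PharmGKB- and
   PubChem-style TSV tables, normalize symbols, merge into one scored
   disease catalog, and intersect disease and compound targets (the Venn
   step). The intersection is the analysis gene list.
2. **PPI network** — from a STRING-format edge list
   (`protein1`, `protein2`, `combined_score` on the 0–1000 scale), keep
   edges with `combined_score >= round(1000 * confidence)` (default
   confidence 0.400) between analysis genes.
3. **Centralities** — degree, betweenness
   (Σ σ<sub>st</sub>(v)/σ<sub>st</sub> over pairs), closeness
   ((k−1)/Σd within each component), eigenvector (principal eigenvector,
   per component, unit norm), LAC (mean induced-neighborhood degree) and
   MCC (Σ (|C|−1)! over maximal cliques C ∋ v).
4. **Critical subnetwork** — two rounds of median filtering: keep nodes
   strictly above the median on *all* of
   degree/betweenness/closeness/eigenvector/LAC, recomputing
   centralities on the shrinking graph between rounds.
5. **Hub genes** — top-10 by Degree and by MCC on the *full* network
   (no intermediate filtering), with shared competition ranks for ties
   and their intersection as the consensus hub set; plus the induced
   hub-neighborhood subnetwork for visualization.
6. **Enrichment** — hypergeometric upper-tail test of the gene list
   against a GMT pathway collection, fold enrichment
   FE = (m/k)/(K/N), Benjamini–Hochberg FDR across the whole tested
   family, and −log10(FDR) for plotting.

A synthetic-data module (`generate_scenario()` / `write_scenario()`)
replaces the live databases: scored gene tables, a scale-free PPI
network with planted hubs, and pathway collections with planted
enrichment at controllable effect size, with the ground truth saved for
recovery testing. See `vignettes/netpharm-methods.Rmd` for the model
and all design decisions.

## Worked example

```r
library(netpharm)

s <- generate_scenario(seed = 1)
s
#> <synthetic_scenario> seed 1: 1000 background genes, 120 disease genes,
#>   90 compound targets, 340 edges, 20 pathways (5 planted), 5 planted hubs

listg <- intersect(s$disease_genes$symbol, s$compound_targets)
g <- build_graph(s$edges, listg, threshold = 0.400)
g
#> <ppi_graph> 85 nodes, 170 edges, confidence >= 0.400
```

Of the 340 generated edges, exactly the 170 true interactions (scores
401–999) survive the 0.400 filter; the 170 decoys (scores 1–399) do not.

```r
core <- extract_core(g, core_config())   # 2 strict rounds, 5 metrics
core
#> <ppi_graph> 7 nodes, 14 edges, confidence >= 0.400

rk_d <- rank_hubs(g, "degree", k = 10)
head(as.data.frame(rk_d), 5)
#>   rank   symbol score
#> 1    1 GENE0630    23
#> 2    2 GENE0029    20
#> 3    3 GENE0104    19
#> 4    4 GENE0371    16
#> 5    5 GENE0040    13

consensus_hubs(rk_d, rank_hubs(g, "mcc", k = 10))
#> "GENE0029" "GENE0040" "GENE0104" "GENE0141" "GENE0371"
#> "GENE0532" "GENE0554" "GENE0557" "GENE0630" "GENE0855"
sort(s$planted_hubs)
#> "GENE0029" "GENE0040" "GENE0104" "GENE0371" "GENE0630"
```

All 5 planted hubs are in the consensus set, and the degree top-5 *are*
the planted hubs. Enrichment separates the 5 planted pathways
(PW001–PW005) from the 15 null pathways by many orders of magnitude:

```r
ora <- run_ora(listg, s$pathways, background = s$universe)
head(as.data.frame(ora)[, c("pathway_id", "n_genes_overlap",
                            "pathway_size", "fold_enrichment", "fdr")], 6)
#>   pathway_id n_genes_overlap pathway_size fold_enrichment          fdr
#> 1      PW001              34           69        5.797101 5.514854e-20
#> 2      PW003              33           66        5.882353 7.127825e-20
#> 3      PW004              24           48        5.882353 3.513954e-14
#> 4      PW005              24           49        5.762305 4.848957e-14
#> 5      PW002              17           34        5.882353 3.827698e-10
#> 6      PW006               7           48        1.715686 2.613228e-01
```

The full pipeline, driven by a JSON config, writes every artifact plus a
manifest:

```sh
Rscript inst/cli/netpharm.R simulate --seed 1 --out-dir demo/inputs
Rscript inst/cli/netpharm.R run --config demo/config.json
```

(Per-stage subcommands `aggregate`, `network`, `centrality`, `core`,
`hubs` and `enrich` expose each stage in isolation; see
`inst/cli/netpharm.R`.)

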