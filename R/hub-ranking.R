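#' Hub-gene ranking
#'
#' Degree and MCC rankings of the full (unfiltered) network, CytoHubba
#' style: hub scores are deliberately computed on the whole PPI graph, not
#' on the median-filtered core, mirroring the published workflow in which
#' hub ranking ran "without the intermediate node filtering".
#'
#' @name hub_ranking
NULL

# Competition ("min") ranks: tied scores share the smallest rank and the
# following rank is skipped, the convention of published hub tables
# (e.g. ranks 4, 4, 6, 6, ...).
competition_ranks <- function(scores) {
  as.integer(rank(-scores, ties.method = "min"))
}

#' Rank hub genes by degree or MCC
#'
#' Nodes are ordered by score descending; the printed order breaks ties
#' lexicographically by symbol for determinism, but tied scores share the
#' same rank number. Every node tied with the k-th score is included, so
#' the table may exceed `k` rows (truncating within a tie would be
#' irreproducible).
#'
#' @param g a `ppi_graph`; scores are computed on this graph as given.
#' @param method `"degree"` or `"mcc"`.
#' @param k number of hub genes requested (default 10).
#' @return an object of class `hub_ranking`: a data.frame with columns
#'   `rank`, `symbol`, `score`, plus attributes `method` and `k`.
#' @export
rank_hubs <- function(g, method = c("degree", "mcc"), k = 10L) {
  method <- match.arg(method)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be >= 1", call. = FALSE)
  nodes <- graph_nodes(g)
  if (length(nodes) == 0L) stop("cannot rank hubs of an empty graph", call. = FALSE)
  scores <- switch(method,
                   degree = as.numeric(degree_centrality(g)[nodes]),
                   mcc = as.numeric(mcc(g)[nodes]))
  ord <- order(-scores, nodes)
  scores <- scores[ord]
  symbols <- nodes[ord]
  if (k > length(symbols)) {
    warning(sprintf("k = %d exceeds node count %d; returning all nodes ranked",
                    k, length(symbols)), call. = FALSE)
    k <- length(symbols)
  }
  cutoff <- scores[k]
  keep <- scores >= cutoff
  out <- data.frame(rank = competition_ranks(scores)[keep],
                    symbol = symbols[keep],
                    score = scores[keep])
  structure(out, class = c("hub_ranking", "data.frame"),
            method = method, k = k)
}

#' @export
print.hub_ranking <- function(x, ...) {
  cat(sprintf("<hub_ranking> method=%s, top %d (%d rows with boundary ties)\n",
              attr(x, "method"), attr(x, "k"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Consensus of two hub rankings
#'
#' @param a,b `hub_ranking` objects (typically degree and MCC on the same
#'   graph).
#' @param rule `"intersection"` (conservative default) or `"union"`.
#' @return sorted character vector of consensus hub symbols.
#' @export
consensus_hubs <- function(a, b, rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  stopifnot(inherits(a, "hub_ranking"), inherits(b, "hub_ranking"))
  sa <- a$symbol
  sb <- b$symbol
  sort(if (rule == "intersection") intersect(sa, sb) else union(sa, sb))
}

#' Hub neighborhood subnetwork
#'
#' Induced subgraph on the hub genes and their first neighbors — the
#' "hub genes and other key genes" interaction view. Export it with
#' [export_graph()].
#'
#' @param g a `ppi_graph`.
#' @param hubs character vector of hub symbols, all present in `g`.
#' @return a `ppi_graph`.
#' @export
hub_subnetwork <- function(g, hubs) {
  ig <- as_igraph(g)
  hubs <- unique(normalize_symbols(hubs))
  missing <- setdiff(hubs, igraph::V(ig)$name)
  if (length(missing)) {
    stop(sprintf("hub gene(s) not in graph: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  idx <- which(igraph::V(ig)$name %in% hubs)
  nbr <- unique(unlist(igraph::adjacent_vertices(ig, idx)))
  keep <- sort(unique(c(igraph::V(ig)$name[idx],
                        if (length(nbr)) igraph::V(ig)$name[nbr])))
  induced_ppi(g, keep)
}

#' Write a hub ranking as a Rank/Name/Score TSV
#'
#' @param ranking a `hub_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hub_ranking <- function(ranking, path) {
  out <- data.frame(Rank = ranking$rank, Name = ranking$symbol,
                    Score = ranking$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
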