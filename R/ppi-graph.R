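#' Protein-protein interaction graphs
#'
#' A `ppi_graph` is a simple undirected [igraph::igraph] over gene symbols,
#' carrying the STRING-style combined confidence score of each interaction
#' as the `combined_score` edge attribute (integer, 0--1000 scale; 400
#' corresponds to "medium confidence" 0.400) plus provenance: the
#' confidence threshold applied at construction and the source the edges
#' came from. Topology is unweighted for all downstream centrality
#' computations; the score is retained only as metadata.
#'
#' @name ppi_graph
NULL

new_ppi_graph <- function(graph, threshold = NA_real_, source = NA_character_) {
  stopifnot(igraph::is_igraph(graph))
  structure(
    list(graph = graph, threshold = threshold, source = source),
    class = "ppi_graph"
  )
}

# Accept either a ppi_graph or a bare igraph in every analysis function.
as_igraph <- function(g) {
  if (inherits(g, "ppi_graph")) return(g$graph)
  if (igraph::is_igraph(g)) return(g)
  stop("expected a `ppi_graph` or an igraph object", call. = FALSE)
}

#' @export
print.ppi_graph <- function(x, ...) {
  ig <- x$graph
  cat(sprintf("<ppi_graph> %d nodes, %d edges", igraph::vcount(ig),
              igraph::ecount(ig)))
  if (!is.na(x$threshold)) cat(sprintf(", confidence >= %.3f", x$threshold))
  cat("\n")
  invisible(x)
}

#' Node symbols of a PPI graph
#' @param g a `ppi_graph` or igraph.
#' @return character vector of gene symbols, lexicographically sorted.
#' @export
graph_nodes <- function(g) {
  sort(igraph::V(as_igraph(g))$name)
}

#' Edge table of a PPI graph
#' @param g a `ppi_graph` or igraph.
#' @return data.frame with columns `protein1`, `protein2`, `combined_score`,
#'   each unordered pair appearing once with `protein1 < protein2`.
#' @export
graph_edges <- function(g) {
  ig <- as_igraph(g)
  if (igraph::ecount(ig) == 0L) {
    return(data.frame(protein1 = character(), protein2 = character(),
                      combined_score = integer()))
  }
  el <- igraph::as_edgelist(ig)
  sc <- igraph::E(ig)$combined_score
  if (is.null(sc)) sc <- rep(NA_integer_, nrow(el))
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  out <- data.frame(protein1 = a, protein2 = b,
                    combined_score = as.integer(sc))
  out[order(out$protein1, out$protein2), , drop = FALSE]
}

#' Read a STRING-format interaction edge list
#'
#' Parses a tab-separated file with columns `protein1`, `protein2` and
#' `combined_score` (integer on the 0--1000 STRING scale). Self-loops are
#' dropped (their count is logged) and duplicate unordered pairs are
#' collapsed keeping the maximum score, so the result describes a simple
#' undirected graph.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `protein1`, `protein2`, `combined_score`.
#' @export
read_string_edges <- function(path) {
  if (!file.exists(path)) stop(sprintf("edge file not found: %s", path), call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  score_raw <- trimws(df$combined_score)
  score <- suppressWarnings(as.numeric(score_raw))
  bad <- which(is.na(score) | score != round(score))
  if (length(bad)) {
    stop(sprintf("%s: non-integer combined_score at data line %d (value '%s')",
                 path, bad[1], score_raw[bad[1]]), call. = FALSE)
  }
  a <- normalize_symbols(df$protein1)
  b <- normalize_symbols(df$protein2)
  self <- a == b
  if (any(self)) np_log("dropped %d self-loop edge(s) from %s", sum(self), path)
  a <- a[!self]; b <- b[!self]; score <- as.integer(score[!self])
  if (length(a) == 0L) {
    return(data.frame(protein1 = character(), protein2 = character(),
                      combined_score = integer()))
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\t")
  # collapse duplicate unordered pairs, keeping the maximum score
  mx <- tapply(score, key, max)
  keys <- names(mx)
  parts <- strsplit(keys, "\t", fixed = TRUE)
  out <- data.frame(
    protein1 = vapply(parts, `[`, "", 1L),
    protein2 = vapply(parts, `[`, "", 2L),
    combined_score = as.integer(mx)
  )
  rownames(out) <- NULL
  out[order(out$protein1, out$protein2), , drop = FALSE]
}

#' Build a confidence-filtered PPI graph
#'
#' Keeps interactions whose combined score reaches `round(1000 * threshold)`
#' (inclusive comparison, matching the STRING web filter) and whose two
#' endpoints both belong to `gene_list`. Genes of the list with no
#' surviving interaction are excluded by default, mirroring the default
#' STRING/Cytoscape view; set `keep_isolates = TRUE` to retain them (they
#' then receive zero centralities downstream).
#'
#' @param edges data.frame as returned by [read_string_edges()].
#' @param gene_list character vector of gene symbols defining the node
#'   universe of the network.
#' @param threshold confidence in `[0, 1]`; default 0.400 ("medium").
#' @param keep_isolates keep list genes without any surviving edge?
#' @param lcc_only restrict to the largest connected component?
#' @param source optional provenance string recorded on the graph.
#' @return a [ppi_graph].
#' @export
build_graph <- function(edges, gene_list, threshold = 0.400,
                        keep_isolates = FALSE, lcc_only = FALSE,
                        source = NA_character_) {
  assert_scalar_number(threshold, "threshold", 0, 1)
  stopifnot(is.data.frame(edges),
            all(c("protein1", "protein2", "combined_score") %in% names(edges)))
  gene_list <- unique(normalize_symbols(gene_list))
  cut <- round(1000 * threshold)
  keep <- edges$combined_score >= cut &
    edges$protein1 %in% gene_list & edges$protein2 %in% gene_list
  kept <- edges[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning(sprintf("no edges survive threshold %.3f within the gene list; graph is empty",
                    threshold), call. = FALSE)
  }
  verts <- if (keep_isolates) gene_list else
    sort(unique(c(kept$protein1, kept$protein2)))
  ig <- igraph::graph_from_data_frame(
    kept[, c("protein1", "protein2")],
    directed = FALSE,
    vertices = data.frame(name = verts)
  )
  igraph::E(ig)$combined_score <- kept$combined_score
  ig <- igraph::simplify(ig, edge.attr.comb = list(combined_score = "max"))
  if (lcc_only && igraph::vcount(ig) > 0L) {
    comp <- igraph::components(ig)
    big <- which.max(comp$csize)
    ig <- igraph::induced_subgraph(ig, which(comp$membership == big))
  }
  new_ppi_graph(ig, threshold = threshold, source = source)
}

#' Export a PPI graph for visualization tools
#'
#' Writes either GraphML (loadable by Cytoscape) or a STRING-style
#' three-column edge TSV that round-trips through [read_string_edges()].
#'
#' @param g a `ppi_graph`.
#' @param path output file path.
#' @param format `"graphml"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("edge-tsv", "graphml")) {
  format <- match.arg(format)
  ig <- as_igraph(g)
  if (igraph::vcount(ig) == 0L) {
    stop("graph is empty; nothing to export (consider lowering the confidence threshold)",
         call. = FALSE)
  }
  if (format == "graphml") {
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    write.table(graph_edges(g), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

# Induced subgraph on a symbol set, preserving provenance.
induced_ppi <- function(g, symbols) {
  ig <- as_igraph(g)
  sub <- igraph::induced_subgraph(ig, which(igraph::V(ig)$name %in% symbols))
  if (inherits(g, "ppi_graph")) {
    new_ppi_graph(sub, threshold = g$threshold, source = g$source)
  } else {
    new_ppi_graph(sub)
  }
}
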