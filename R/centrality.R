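#' Node centrality measures
#'
#' The six centralities used throughout the pipeline. Degree, betweenness,
#' closeness, eigenvector and LAC are the panel used for iterated median
#' filtering (the CytoNCA panel); degree and MCC are the two hub-ranking
#' scores (the CytoHubba pair). All measures treat the graph as undirected
#' and unweighted; edge confidence scores are metadata only.
#'
#' @name centrality
NULL

#' Degree centrality
#'
#' Number of immediate neighbors of each node.
#'
#' @param g a `ppi_graph` or igraph.
#' @return named integer vector over all nodes.
#' @export
degree_centrality <- function(g) {
  ig <- as_igraph(g)
  d <- igraph::degree(ig, loops = FALSE)
  setNames(as.integer(d), igraph::V(ig)$name)
}

#' Betweenness centrality
#'
#' For node `v`, the sum over unordered pairs `{s, t}` (both distinct from
#' `v`) of the fraction of shortest `s`--`t` paths passing through `v`.
#' Reported unnormalized by default (the CytoNCA convention);
#' `normalized = TRUE` divides by `(n-1)(n-2)/2`. The downstream median
#' filter is invariant to this monotone rescaling.
#'
#' @param g a `ppi_graph` or igraph.
#' @param normalized divide by the number of possible pairs?
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(g, normalized = FALSE) {
  ig <- as_igraph(g)
  b <- igraph::betweenness(ig, directed = FALSE, weights = NA)
  n <- igraph::vcount(ig)
  if (normalized) {
    b <- if (n > 2) b / ((n - 1) * (n - 2) / 2) else b * 0
  }
  setNames(as.numeric(b), igraph::V(ig)$name)
}

#' Closeness centrality
#'
#' Reciprocal of the average shortest-path distance from a node to the
#' other nodes. On a disconnected graph the average is taken within the
#' node's connected component: for a component of size `k >= 2`,
#' `closeness(v) = (k - 1) / sum(d(v, u))`; singleton components score 0.
#' `harmonic = TRUE` instead returns the mean of `1/d(v, u)` over all other
#' nodes in the graph (unreachable nodes contribute 0), an alternative that
#' is well defined globally.
#'
#' @param g a `ppi_graph` or igraph.
#' @param harmonic use harmonic closeness instead of the per-component
#'   average-distance form?
#' @return named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(g, harmonic = FALSE) {
  ig <- as_igraph(g)
  n <- igraph::vcount(ig)
  nm <- igraph::V(ig)$name
  if (n == 0L) return(setNames(numeric(0), character(0)))
  d <- igraph::distances(ig, weights = NA)
  out <- numeric(n)
  if (harmonic) {
    inv <- 1 / d
    diag(inv) <- 0
    inv[is.infinite(d)] <- 0
    out <- if (n > 1) rowSums(inv) / (n - 1) else rep(0, n)
  } else {
    comp <- igraph::components(ig)
    for (v in seq_len(n)) {
      members <- comp$membership == comp$membership[v]
      k <- sum(members)
      out[v] <- if (k < 2) 0 else (k - 1) / sum(d[v, members])
    }
  }
  setNames(out, nm)
}

#' Eigenvector centrality
#'
#' Principal-eigenvector scores of the adjacency matrix, computed
#' independently on each connected component by shifted power iteration
#' (iterating `A + I`, which leaves eigenvectors unchanged but makes the
#' dominant eigenvalue strictly largest in modulus, so the iteration also
#' converges on bipartite components). Scores are nonnegative and scaled
#' to unit Euclidean norm within each component; the start vector is
#' all-ones, making the result deterministic. Edgeless components score 0.
#'
#' @param g a `ppi_graph` or igraph.
#' @param tol convergence tolerance on the max-norm change between
#'   successive normalized iterates.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return named numeric vector.
#' @export
eigenvector_centrality <- function(g, tol = 1e-10, max_iter = 10000L) {
  ig <- as_igraph(g)
  n <- igraph::vcount(ig)
  nm <- igraph::V(ig)$name
  out <- setNames(numeric(n), nm)
  if (n == 0L) return(out)
  comp <- igraph::components(ig)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(ig, idx)
    if (igraph::ecount(sub) == 0L) next
    A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    x <- rep(1, length(idx)) / sqrt(length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      y <- as.numeric(A %*% x) + x    # (A + I) x
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < tol) {
        x <- y
        converged <- TRUE
        break
      }
      x <- y
    }
    if (!converged) {
      stop(sprintf("eigenvector centrality did not converge within %d iterations (component of %d nodes)",
                   max_iter, length(idx)), call. = FALSE)
    }
    out[igraph::V(sub)$name] <- x
  }
  out
}

#' Local average connectivity (LAC)
#'
#' For node `v` with neighborhood `N(v)`, the mean degree of `v`'s
#' neighbors within the subgraph induced by `N(v)` (the node itself
#' excluded). High LAC means the neighbors are densely interconnected.
#' Isolated nodes score 0.
#'
#' @param g a `ppi_graph` or igraph.
#' @return named numeric vector.
#' @export
lac <- function(g) {
  ig <- as_igraph(g)
  n <- igraph::vcount(ig)
  nm <- igraph::V(ig)$name
  out <- setNames(numeric(n), nm)
  if (n == 0L) return(out)
  adj <- igraph::as_adj_list(ig, mode = "all")
  for (v in seq_len(n)) {
    nb <- as.integer(adj[[v]])
    nb <- setdiff(unique(nb), v)
    if (length(nb) == 0L) next
    sub <- igraph::induced_subgraph(ig, nb)
    out[v] <- sum(igraph::degree(sub)) / length(nb)
  }
  out
}

#' Maximal clique centrality (MCC)
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over all maximal cliques `C`
#' containing `v`, computed by exact maximal-clique enumeration
#' (Bron--Kerbosch with pivoting, via [igraph::max_cliques()]). For a node
#' whose every maximal clique is a single edge, MCC equals its degree.
#' Isolated nodes score 0.
#'
#' @param g a `ppi_graph` or igraph.
#' @param max_cliques cap on the number of maximal cliques; exceeding it
#'   aborts (guards pathological dense inputs). Raise it explicitly if a
#'   legitimate graph trips the guard.
#' @return named numeric vector of nonnegative integers (stored as double:
#'   factorials overflow R integers quickly).
#' @export
mcc <- function(g, max_cliques = 200000L) {
  ig <- as_igraph(g)
  n <- igraph::vcount(ig)
  nm <- igraph::V(ig)$name
  out <- setNames(numeric(n), nm)
  if (n == 0L || igraph::ecount(ig) == 0L) return(out)
  cl <- igraph::max_cliques(ig, min = 2)
  if (length(cl) > max_cliques) {
    stop(sprintf("graph has more than %d maximal cliques; raise `max_cliques` to proceed",
                 max_cliques), call. = FALSE)
  }
  for (C in cl) {
    w <- factorial(length(C) - 1L)
    out[as.integer(C)] <- out[as.integer(C)] + w
  }
  out
}

#' Full centrality profile of every node
#'
#' Computes all six measures and assembles one row per node, in
#' deterministic lexicographic node order.
#'
#' @param g a `ppi_graph` or igraph.
#' @param betweenness_normalized passed to [betweenness_centrality()].
#' @param harmonic_closeness passed to [closeness_centrality()].
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`, `lac`, `mcc`.
#' @export
profile_all <- function(g, betweenness_normalized = FALSE,
                        harmonic_closeness = FALSE) {
  ig <- as_igraph(g)
  nodes <- sort(igraph::V(ig)$name)
  if (length(nodes) == 0L) {
    return(data.frame(node = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric(),
                      eigenvector = numeric(), lac = numeric(),
                      mcc = numeric()))
  }
  eig <- if (igraph::ecount(ig) > 0L) eigenvector_centrality(ig) else
    setNames(numeric(length(nodes)), igraph::V(ig)$name)
  data.frame(
    node = nodes,
    degree = degree_centrality(ig)[nodes],
    betweenness = betweenness_centrality(ig, normalized = betweenness_normalized)[nodes],
    closeness = closeness_centrality(ig, harmonic = harmonic_closeness)[nodes],
    eigenvector = eig[nodes],
    lac = lac(ig)[nodes],
    mcc = mcc(ig)[nodes],
    row.names = NULL
  )
}

#' Write a centrality profile table
#'
#' @param profiles data.frame from [profile_all()].
#' @param path output TSV path; reals are printed with 6 significant digits.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  for (col in c("betweenness", "closeness", "eigenvector", "lac", "mcc")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
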