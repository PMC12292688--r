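# Small-graph fixtures and brute-force centrality oracles.
#
# The oracles work from a plain adjacency matrix and never call the
# package's centrality code (nor igraph), so they are an independent
# check, not a restatement.

# Build a ppi_graph from a flat vector of symbol pairs, e.g.
# toy_graph(c("A","B", "B","C")) gives the path A-B-C.
toy_graph <- function(pairs, scores = NULL, nodes = NULL) {
  stopifnot(length(pairs) %% 2 == 0)
  a <- pairs[seq(1, length(pairs), by = 2)]
  b <- pairs[seq(2, length(pairs), by = 2)]
  if (is.null(scores)) scores <- rep(900L, length(a))
  edges <- data.frame(protein1 = a, protein2 = b, combined_score = scores)
  build_graph(edges, gene_list = unique(c(a, b, nodes)), threshold = 0,
              keep_isolates = !is.null(nodes))
}

# Erdos-Renyi-ish random edge table over n nodes under a fixed seed.
random_edge_table <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(protein1 = pairs[keep, 1], protein2 = pairs[keep, 2],
             combined_score = 900L)
}

random_toy_graph <- function(n, p, seed) {
  et <- random_edge_table(n, p, seed)
  build_graph(et, gene_list = sprintf("N%02d", seq_len(n)), threshold = 0,
              keep_isolates = TRUE)
}

# ---- adjacency-matrix extraction (bookkeeping, not an algorithm) --------

adj_matrix <- function(g) {
  nodes <- graph_nodes(g)
  ed <- graph_edges(g)
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(ed))) {
    A[ed$protein1[i], ed$protein2[i]] <- 1L
    A[ed$protein2[i], ed$protein1[i]] <- 1L
  }
  A
}

# ---- oracles ------------------------------------------------------------

# All-pairs shortest-path distances by hand-rolled BFS.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(A[u, ] == 1L)) {
          if (is.infinite(dist[v])) { dist[v] <- dist[u] + 1; nxt <- c(nxt, v) }
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# Closeness: within-component (k-1)/sum(d); singletons 0.
oracle_closeness <- function(g) {
  A <- adj_matrix(g)
  D <- oracle_distances(A)
  n <- nrow(A)
  out <- setNames(numeric(n), rownames(A))
  for (v in seq_len(n)) {
    comp <- which(is.finite(D[v, ]))
    k <- length(comp)
    out[v] <- if (k < 2) 0 else (k - 1) / sum(D[v, comp])
  }
  out
}

# Betweenness by exhaustive enumeration of all geodesics: depth-bounded
# DFS over simple paths of exactly the shortest length.
oracle_betweenness <- function(g) {
  A <- adj_matrix(g)
  D <- oracle_distances(A)
  n <- nrow(A)
  out <- setNames(numeric(n), rownames(A))
  enumerate_geodesics <- function(s, t, len) {
    paths <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) {
        if (length(path) - 1L == len) paths[[length(paths) + 1L]] <<- path
        return()
      }
      if (length(path) - 1L >= len) return()
      for (v in which(A[u, ] == 1L)) {
        if (!(v %in% path)) walk(c(path, v))
      }
    }
    walk(s)
    paths
  }
  for (s in seq_len(n - 1L)) for (t in seq(s + 1L, n)) {
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    geos <- enumerate_geodesics(s, t, D[s, t])
    sigma <- length(geos)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(geos, function(p) v %in% p[-c(1, length(p))], TRUE))
      out[v] <- out[v] + through / sigma
    }
  }
  out
}

# LAC by direct recomputation on the adjacency matrix.
oracle_lac <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  out <- setNames(numeric(n), rownames(A))
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1L)
    if (length(nb) == 0L) next
    sub <- A[nb, nb, drop = FALSE]
    out[v] <- sum(sub) / length(nb)  # sum of induced degrees / |N(v)|
  }
  out
}

# MCC by subset enumeration: test every vertex subset for clique-ness and
# maximality (feasible for n <= 12).
oracle_mcc <- function(g) {
  A <- adj_matrix(g)
  n <- nrow(A)
  out <- setNames(numeric(n), rownames(A))
  is_clique <- function(S) {
    if (length(S) < 2) return(FALSE)
    all(A[S, S][upper.tri(diag(length(S)))] == 1L)
  }
  for (code in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (!is_clique(S)) next
    extendable <- any(vapply(setdiff(seq_len(n), S),
                             function(u) all(A[u, S] == 1L), TRUE))
    if (extendable) next
    out[S] <- out[S] + factorial(length(S) - 1L)
  }
  out
}

# Eigenvector by dense eigen-decomposition, per connected component.
oracle_eigenvector <- function(g) {
  A <- adj_matrix(g)
  D <- oracle_distances(A)
  n <- nrow(A)
  out <- setNames(numeric(n), rownames(A))
  seen <- rep(FALSE, n)
  for (v in seq_len(n)) {
    if (seen[v]) next
    comp <- which(is.finite(D[v, ]))
    seen[comp] <- TRUE
    sub <- A[comp, comp, drop = FALSE]
    if (sum(sub) == 0) next
    es <- eigen(sub, symmetric = TRUE)
    x <- abs(es$vectors[, 1])
    out[comp] <- x / sqrt(sum(x^2))
  }
  out
}
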