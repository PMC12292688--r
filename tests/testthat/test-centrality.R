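triangle <- toy_graph(c("A","B", "B","C", "A","C"))
star3 <- toy_graph(c("C","X", "C","Y", "C","Z"))       # center C, 3 leaves
star4 <- toy_graph(c("C","W", "C","X", "C","Y", "C","Z"))
path3 <- toy_graph(c("A","B", "B","C"))
k4 <- toy_graph(c("A","B","A","C","A","D","B","C","B","D","C","D"))

test_that("degree centrality matches hand-worked cases and the handshake lemma", {
  expect_equal(degree_centrality(triangle), c(A = 2L, B = 2L, C = 2L))
  expect_equal(degree_centrality(star3)[["C"]], 3L)
  expect_equal(degree_centrality(star3)[["X"]], 1L)
  iso <- toy_graph(c("A","B"), nodes = "Z")
  expect_equal(degree_centrality(iso)[["Z"]], 0L)
  for (seed in 1:5) {
    g <- random_toy_graph(10, 0.3, seed)
    expect_equal(sum(degree_centrality(g)), 2L * nrow(graph_edges(g)))
  }
})

test_that("betweenness matches hand-worked cases", {
  b <- betweenness_centrality(star3)
  expect_equal(b[["C"]], 3)          # all three leaf pairs route via C
  expect_equal(b[["X"]], 0)
  expect_equal(betweenness_centrality(path3)[["B"]], 1)
  bn <- betweenness_centrality(star3, normalized = TRUE)
  expect_equal(bn[["C"]], 1)         # 3 / ((4-1)(4-2)/2)
})

test_that("closeness follows the within-component convention", {
  cl <- closeness_centrality(path3)
  expect_equal(cl[["B"]], 1)
  expect_equal(cl[["A"]], 2/3)
  expect_equal(unname(closeness_centrality(k4)), rep(1, 4))
  two_edges <- toy_graph(c("A","B", "C","D"))
  expect_equal(unname(closeness_centrality(two_edges)), rep(1, 4))
  singleton <- toy_graph(c("A","B"), nodes = "Z")
  expect_equal(closeness_centrality(singleton)[["Z"]], 0)
})

test_that("harmonic closeness counts unreachable nodes as zero contribution", {
  two_edges <- toy_graph(c("A","B", "C","D"))
  # each node: one neighbor at distance 1, two unreachable -> 1/3
  expect_equal(unname(closeness_centrality(two_edges, harmonic = TRUE)),
               rep(1/3, 4))
})

test_that("eigenvector centrality matches analytic values", {
  e <- eigenvector_centrality(triangle)
  expect_equal(unname(e), rep(1/sqrt(3), 3), tolerance = 1e-8)
  e4 <- eigenvector_centrality(star4)
  expect_equal(e4[["C"]] / e4[["X"]], 2, tolerance = 1e-8)  # sqrt(n-1), n-1 = 4
  # locality: two identical components score like the single-component case
  twin <- toy_graph(c("A","B","B","C","A","C", "D","E","E","F","D","F"))
  et <- eigenvector_centrality(twin)
  expect_equal(unname(et), rep(1/sqrt(3), 6), tolerance = 1e-8)
})

test_that("LAC matches hand-worked cases", {
  expect_equal(unname(lac(k4)), rep(2, 4))
  expect_equal(lac(star3)[["C"]], 0)
  expect_equal(unname(lac(triangle)), rep(1, 3))
})

test_that("MCC matches hand-worked cases", {
  expect_equal(unname(mcc(triangle)), rep(2, 3))
  expect_equal(mcc(star3)[["C"]], 3)   # equals degree when cliques are edges
  expect_equal(unname(mcc(k4)), rep(6, 4))
  iso <- toy_graph(c("A","B"), nodes = "Z")
  expect_equal(mcc(iso)[["Z"]], 0)
})

test_that("MCC honors the maximal-clique cap", {
  expect_error(mcc(k4, max_cliques = 0L), "maximal cliques")
})

test_that("profile_all composes the per-measure values in lexicographic order", {
  p <- profile_all(triangle)
  expect_equal(p$node, c("A", "B", "C"))
  expect_equal(p$degree, rep(2L, 3))
  expect_equal(p$betweenness, rep(0, 3))
  expect_equal(p$closeness, rep(1, 3))
  expect_equal(p$lac, rep(1, 3))
  expect_equal(p$mcc, rep(2, 3))
  star_row <- profile_all(star3)
  crow <- star_row[star_row$node == "C", ]
  expect_equal(crow$degree, 3L)
  expect_equal(crow$lac, 0)
  expect_equal(crow$mcc, 3)
  expect_warning(
    empty <- build_graph(data.frame(protein1 = character(),
                                    protein2 = character(),
                                    combined_score = integer()),
                         gene_list = character()),
    "empty")
  expect_equal(nrow(profile_all(empty)), 0L)
})

test_that("centralities match brute-force oracles on random small graphs", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:12, 1)
    g <- random_toy_graph(n, runif(1, 0.2, 0.6), seed)
    expect_equal(betweenness_centrality(g), oracle_betweenness(g),
                 tolerance = 1e-9, info = paste("seed", seed))
    expect_equal(closeness_centrality(g), oracle_closeness(g),
                 tolerance = 1e-9, info = paste("seed", seed))
    expect_equal(lac(g), oracle_lac(g), tolerance = 1e-9,
                 info = paste("seed", seed))
    expect_identical(unname(mcc(g)), unname(oracle_mcc(g)),
                     info = paste("seed", seed))
  }
})

test_that("power iteration agrees with dense eigen-decomposition", {
  for (seed in 1:10) {
    set.seed(seed)
    g <- random_toy_graph(sample(10:50, 1), 0.15, seed + 100)
    expect_equal(eigenvector_centrality(g, tol = 1e-10),
                 oracle_eigenvector(g), tolerance = 1e-6,
                 info = paste("seed", seed))
  }
})

test_that("centrality maps are invariant under node relabeling", {
  base <- random_edge_table(9, 0.35, 7)
  set.seed(11)
  perm_names <- setNames(sprintf("P%02d", sample(9)), sprintf("N%02d", 1:9))
  permuted <- data.frame(protein1 = unname(perm_names[base$protein1]),
                         protein2 = unname(perm_names[base$protein2]),
                         combined_score = base$combined_score)
  g1 <- build_graph(base, sprintf("N%02d", 1:9), 0, keep_isolates = TRUE)
  g2 <- build_graph(permuted, unname(perm_names), 0, keep_isolates = TRUE)
  p1 <- profile_all(g1)
  p2 <- profile_all(g2)
  p1$node <- unname(perm_names[p1$node])
  p1 <- p1[order(p1$node), ]
  rownames(p1) <- rownames(p2) <- NULL
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("adding an edge never decreases either endpoint's degree or MCC", {
  for (seed in 1:10) {
    et <- random_edge_table(8, 0.3, seed + 40)
    nodes <- sprintf("N%02d", 1:8)
    g <- build_graph(et, nodes, 0, keep_isolates = TRUE)
    present <- paste(graph_edges(g)$protein1, graph_edges(g)$protein2)
    all_pairs <- t(combn(nodes, 2))
    free <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% present), ,
                      drop = FALSE]
    if (nrow(free) == 0L) next
    pick <- free[1, ]
    et2 <- rbind(et, data.frame(protein1 = pick[1], protein2 = pick[2],
                                combined_score = 900L))
    g2 <- build_graph(et2, nodes, 0, keep_isolates = TRUE)
    for (v in pick) {
      expect_gte(degree_centrality(g2)[[v]], degree_centrality(g)[[v]])
      expect_gte(mcc(g2)[[v]], mcc(g)[[v]])
    }
  }
})
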