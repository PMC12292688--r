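published_table <- read.delim(system.file("extdata",
                                          "published_enrichment_table.tsv",
                                          package = "netpharm"))

test_that("read_gmt parses, de-duplicates and validates", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc one\tA\tB\ta", "P2\tdesc two\tC\tD\tE"), p)
  pw <- read_gmt(p)
  expect_length(pw, 2)
  expect_equal(pw$P1, c("A", "B"))
  expect_equal(unname(attr(pw, "description")["P2"]), "desc two")
  bad <- tempfile(fileext = ".gmt")
  writeLines(c("P1\tdesc\tA", "P2\tonly-two-fields"), bad)
  expect_error(read_gmt(bad), "line 2")
  empty <- tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_warning(pw0 <- read_gmt(empty), "empty")
  expect_length(pw0, 0)
})

test_that("hypergeometric upper-tail p-values are exact", {
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_pvalue(0, 5, 5, 10), 1.0)
  for (K in c(3, 7)) {
    expect_equal(hypergeom_pvalue(1, 1, K, 20), K / 20, tolerance = 1e-12)
  }
  # independent oracle: direct summation of the mass function via choose()
  brute <- function(m, k, K, N) {
    sum(vapply(m:min(k, K),
               function(i) choose(K, i) * choose(N - K, k - i) / choose(N, k),
               0))
  }
  set.seed(8)
  for (i in 1:25) {
    N <- sample(10:60, 1); K <- sample(1:N, 1); k <- sample(1:N, 1)
    m <- sample(0:min(k, K), 1)
    expect_equal(hypergeom_pvalue(m, k, K, N), brute(max(m, 1), k, K, N) +
                   (if (m == 0) 1 - brute(1, k, K, N) else 0),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_pvalue(6, 5, 5, 10), "infeasible")
  expect_error(hypergeom_pvalue(2, 5, 5, 4), "infeasible")
})

test_that("p-value is strictly decreasing in the overlap", {
  p_prev <- Inf
  for (m in 0:8) {
    p <- hypergeom_pvalue(m, 10, 20, 100)
    expect_lt(p, p_prev + 1e-15)
    if (m > 0) expect_lt(p, p_prev)
    p_prev <- p
  }
})

test_that("fold enrichment is (m/k)/(K/N)", {
  expect_equal(fold_enrichment(5, 50, 100, 10000), 10.0)
  expect_equal(fold_enrichment(0, 10, 10, 100), 0.0)
  # a published row: m = 6, K = 50 with background/list ratio 422.3
  expect_equal(round(422.3 * 6 / 50, 1), 50.7)
  expect_equal(round(fold_enrichment(6, 10, 50, 4223), 1), 50.7)
  expect_error(fold_enrichment(1, 0, 5, 10), "positive")
})

test_that("BH adjustment matches hand-worked cases and its properties", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
})

test_that("run_ora computes the worked example and filters by overlap", {
  pw <- structure(list(P1 = c("A", "B", "C"), P2 = c("X", "Y", "Z")),
                  class = "pathway_collection")
  bg <- c("A", "B", "C", "X", "Y", "Z", "U1", "U2", "U3", "U4")
  res <- run_ora(c("A", "B", "C"), pw, background = bg, min_overlap = 1)
  expect_equal(nrow(res), 1L)
  expect_equal(res$pathway_id, "P1")
  expect_equal(res$n_genes_overlap, 3L)
  expect_equal(res$fold_enrichment, 10 / 3)
  expect_equal(res$p_value, 1 / choose(10, 3) * choose(7, 0) * choose(3, 3))
  expect_equal(res$neg_log10_fdr, -log10(res$fdr))
  expect_gte(res$fdr, res$p_value)
})

test_that("FDR is adjusted across the whole tested family, order-invariantly", {
  set.seed(12)
  s <- generate_scenario(seed = 12)
  listg <- intersect(s$disease_genes$symbol, s$compound_targets)
  r1 <- run_ora(listg, s$pathways, background = s$universe)
  r2 <- run_ora(listg, s$pathways[rev(seq_along(s$pathways))],
                background = s$universe)
  expect_equal(r1, r2, ignore_attr = TRUE)
  # family = all testable pathways, not only reported rows
  all_rows <- run_ora(listg, s$pathways, background = s$universe,
                      min_overlap = 0)
  expect_equal(r1$fdr, all_rows$fdr[match(r1$pathway_id, all_rows$pathway_id)])
})

test_that("run_ora validates its inputs", {
  pw <- structure(list(P1 = c("A", "B")), class = "pathway_collection")
  expect_error(run_ora(c("A", "QQQ"), pw, background = c("A", "B", "C")),
               "outside the background")
  expect_error(run_ora("A", pw, background = character(0)), "empty")
})

test_that("pathway members outside the background are ignored before testing", {
  pw <- structure(list(P1 = c("A", "B", "NOT_IN_BG")),
                  class = "pathway_collection")
  bg <- c("A", "B", "C", "D")
  res <- run_ora(c("A", "B"), pw, background = bg, min_overlap = 1)
  expect_equal(res$pathway_size, 2L)
})

test_that("export_enrichment writes the published column layout", {
  pw <- structure(list(P1 = c("A", "B", "C")), class = "pathway_collection")
  bg <- c("A", "B", "C", sprintf("U%d", 1:7))
  res <- run_ora(c("A", "B", "C"), pw, background = bg, min_overlap = 1)
  p <- tempfile(fileext = ".tsv")
  export_enrichment(res, p)
  back <- read.delim(p, check.names = FALSE, colClasses = "character")
  expect_equal(names(back)[1:5],
               c("enrichment_fdr", "n_genes", "pathway_genes",
                 "fold_enrichment", "pathways"))
  expect_match(back$enrichment_fdr[1], "e-0?\\d")
  expect_equal(as.numeric(back$fold_enrichment[1]), round(10 / 3, 1))
  # empty result still yields a header-only file
  empty <- res[0, ]
  p2 <- tempfile(fileext = ".tsv")
  export_enrichment(empty, p2)
  expect_equal(nrow(read.delim(p2, check.names = FALSE)), 0L)
})

test_that("neg_log10_fdr is the log identity", {
  expect_equal(-log10(1e-10), 10)
  pw <- structure(list(P1 = LETTERS[1:5]), class = "pathway_collection")
  bg <- c(LETTERS[1:5], sprintf("U%d", 1:95))
  res <- run_ora(LETTERS[1:5], pw, background = bg, min_overlap = 1)
  expect_equal(res$neg_log10_fdr, -log10(res$fdr))
})

test_that("the published enrichment table is internally consistent", {
  chk <- crosscheck_fold_enrichment(published_table)
  expect_true(all(abs(chk$predicted_fold_enrichment -
                        chk$fold_enrichment) <= 0.2))
  expect_true(all(chk$fitted_ratio >= 421.5 & chk$fitted_ratio <= 423.0))
})
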