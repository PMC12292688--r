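#' Pathway over-representation analysis
#'
#' Hypergeometric ORA of a gene list against a GMT pathway collection:
#' for each pathway with `K` background members, list size `k` and
#' background size `N`, the overlap `m` is scored by the upper-tail
#' hypergeometric probability `P(X >= m)`, adjusted across the whole test
#' family by Benjamini-Hochberg, and summarized by the fold enrichment
#' `(m/k) / (K/N)` — the fraction of the list inside the pathway divided
#' by the corresponding background fraction.
#'
#' @name enrichment
NULL

#' Read a GMT pathway collection
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' `name`, `description`, members... Member symbols are uppercased and
#' de-duplicated within each line.
#'
#' @param path GMT file path.
#' @return a named list of character vectors (members by pathway id) with
#'   a `"description"` attribute; class `pathway_collection`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning(sprintf("%s: empty GMT file", path), call. = FALSE)
    out <- structure(list(), description = character(0))
    class(out) <- "pathway_collection"
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad)) {
    stop(sprintf("%s: malformed GMT line %d (need name, description and >= 1 member)",
                 path, bad[1]), call. = FALSE)
  }
  ids <- vapply(parts, `[`, "", 1L)
  desc <- vapply(parts, `[`, "", 2L)
  out <- lapply(parts, function(f) sort(unique(normalize_symbols(f[-(1:2)]))))
  names(out) <- ids
  attr(out, "description") <- setNames(desc, ids)
  class(out) <- "pathway_collection"
  out
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= m)` for `X ~ Hypergeometric(N, K, k)`: the probability of
#' drawing at least `m` pathway genes when `k` genes are drawn without
#' replacement from a background of `N` genes of which `K` belong to the
#' pathway. Exact (computed through the log-space hypergeometric CDF).
#'
#' @param m observed overlap.
#' @param k list size (number of draws).
#' @param K pathway size within the background.
#' @param N background size.
#' @return p-value in `(0, 1]`.
#' @export
hypergeom_pvalue <- function(m, k, K, N) {
  for (v in list(m = m, k = k, K = K, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != round(v)) {
      stop("all of m, k, K, N must be single nonnegative integers", call. = FALSE)
    }
  }
  if (m > min(k, K) || k > N || K > N) {
    stop(sprintf("infeasible counts: m=%d k=%d K=%d N=%d", m, k, K, N),
         call. = FALSE)
  }
  if (m == 0) return(1.0)
  stats::phyper(m - 1, K, N - K, k, lower.tail = FALSE)
}

#' Fold enrichment
#'
#' `(m/k) / (K/N)`: how many times more frequent pathway genes are in the
#' list than in the background. Zero iff the overlap is zero.
#'
#' @inheritParams hypergeom_pvalue
#' @return positive real (0 when `m = 0`).
#' @export
fold_enrichment <- function(m, k, K, N) {
  if (any(c(k, K, N) <= 0)) stop("k, K and N must be positive", call. = FALSE)
  if (m < 0) stop("m must be nonnegative", call. = FALSE)
  (m / k) / (K / N)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: values are clipped to 1, monotone
#' nondecreasing in sorted order, and returned in the input order.
#'
#' @param pvalues numeric vector with all values in `(0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run over-representation analysis
#'
#' Every pathway with at least one member inside the background is tested
#' (its member set is first intersected with the background); FDR is
#' adjusted across this whole family. Rows are then restricted to
#' pathways with overlap `>= min_overlap` and sorted by FDR ascending
#' (ties broken by pathway id).
#'
#' @param gene_list character vector of analysis genes, a subset of
#'   `background`.
#' @param pathways a `pathway_collection` from [read_gmt()] or a named
#'   list of member vectors.
#' @param background character vector: the gene universe. Defaults to the
#'   union of all pathway members.
#' @param min_overlap minimum overlap for a pathway to be reported
#'   (default 2).
#' @return an `enrichment_result` data.frame with columns `pathway_id`,
#'   `name`, `n_genes_overlap`, `pathway_size`, `list_size`,
#'   `background_size`, `fold_enrichment`, `p_value`, `fdr`,
#'   `neg_log10_fdr`.
#' @export
run_ora <- function(gene_list, pathways, background = NULL, min_overlap = 2L) {
  gene_list <- unique(normalize_symbols(gene_list))
  desc <- attr(pathways, "description")
  if (is.null(background)) {
    background <- unique(unlist(pathways, use.names = FALSE))
  }
  background <- unique(normalize_symbols(background))
  if (length(background) == 0L) stop("background universe is empty", call. = FALSE)
  outside <- setdiff(gene_list, background)
  if (length(outside)) {
    stop(sprintf("%d gene(s) of the list are outside the background (e.g. %s)",
                 length(outside), outside[1]), call. = FALSE)
  }
  if (min_overlap < 0) stop("`min_overlap` must be >= 0", call. = FALSE)
  N <- length(background)
  k <- length(gene_list)
  ids <- names(pathways)
  members <- lapply(pathways, function(ms) intersect(ms, background))
  K <- vapply(members, length, 0L)
  testable <- K > 0L
  ids <- ids[testable]; members <- members[testable]; K <- K[testable]
  m <- vapply(members, function(ms) length(intersect(ms, gene_list)), 0L)
  p <- vapply(seq_along(ids), function(i) hypergeom_pvalue(m[i], k, K[i], N), 0)
  fdr <- bh_fdr(p)
  fe <- vapply(seq_along(ids), function(i) fold_enrichment(m[i], k, K[i], N), 0)
  out <- data.frame(
    pathway_id = ids,
    name = if (is.null(desc)) ids else unname(desc[ids]),
    n_genes_overlap = m,
    pathway_size = K,
    list_size = k,
    background_size = N,
    fold_enrichment = fe,
    p_value = p,
    fdr = fdr,
    neg_log10_fdr = -log10(fdr),
    row.names = NULL
  )
  out <- out[out$n_genes_overlap >= min_overlap, , drop = FALSE]
  out <- out[order(out$fdr, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Export an enrichment table
#'
#' Writes the published-table column layout (`Enrichment FDR`,
#' `No. of Genes`, `Pathway Genes`, `Fold Enrichment`, `Pathways`) plus
#' the machine-readable extras `pathway_id`, `p_value` and
#' `neg_log10_fdr`. FDR is printed in scientific notation and fold
#' enrichment to one decimal place.
#'
#' @param rows an `enrichment_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_enrichment <- function(rows, path) {
  out <- data.frame(
    enrichment_fdr = sprintf("%.1e", rows$fdr),
    n_genes = rows$n_genes_overlap,
    pathway_genes = rows$pathway_size,
    fold_enrichment = sprintf("%.1f", rows$fold_enrichment),
    pathways = rows$name,
    pathway_id = rows$pathway_id,
    p_value = sprintf("%.3e", rows$p_value),
    neg_log10_fdr = sprintf("%.4f", rows$neg_log10_fdr),
    check.names = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-check the internal consistency of a published enrichment table
#'
#' A published ORA table usually omits the list size `k` and background
#' size `N`, but fold enrichment `FE = (m/k)/(K/N) = (N/k) * m/K` depends
#' on them only through the single ratio `r = N/k`. Each row therefore
#' implies `r = FE * K / m`, and a self-consistent table has one common
#' ratio. For every row this function estimates `r` from the *other* rows
#' (median of their implied ratios, a leave-one-out fit) and predicts the
#' row's fold enrichment as `r * m / K`.
#'
#' @param table data.frame with columns `n_genes` (overlap `m`),
#'   `pathway_genes` (`K`) and `fold_enrichment` (printed FE).
#' @return the input with extra columns `implied_ratio`, `fitted_ratio`
#'   (leave-one-out) and `predicted_fold_enrichment`.
#' @export
crosscheck_fold_enrichment <- function(table) {
  need <- c("n_genes", "pathway_genes", "fold_enrichment")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(table) < 2L) stop("need at least two rows to cross-check", call. = FALSE)
  m <- table$n_genes
  K <- table$pathway_genes
  fe <- table$fold_enrichment
  implied <- fe * K / m
  fitted <- vapply(seq_len(nrow(table)),
                   function(i) median(implied[-i]), 0)
  table$implied_ratio <- implied
  table$fitted_ratio <- fitted
  table$predicted_fold_enrichment <- fitted * m / K
  table
}
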