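#' Multi-source gene catalogs
#'
#' Readers for the four target-gene source tables (a GeneCards-style
#' scored disease-gene table, a DrugBank-style drug-target table, and
#' PharmGKB/PubChem-style plain gene tables), a merger producing one
#' scored catalog, and the disease/compound target intersection (the Venn
#' step of the workflow). A catalog is a data.frame with columns `symbol`
#' (uppercase, unique), `relevance_score` (numeric, `NA` unless the gene
#' carries a GeneCards-style score) and `sources` (list column of source
#' tags).
#'
#' @name gene_catalog
NULL

catalog_sources <- c("genecards", "drugbank", "pharmgkb", "pubchem")

new_catalog <- function(symbol, relevance_score, sources) {
  df <- data.frame(symbol = symbol, relevance_score = relevance_score)
  df$sources <- sources
  class(df) <- c("gene_catalog", "data.frame")
  df
}

#' Read one source table into a gene catalog
#'
#' Expected columns by source: `genecards`: `symbol`, `relevance_score`;
#' `drugbank`: `drug`, `target`; `pharmgkb` and `pubchem`: `symbol`.
#' Symbols are uppercased and trimmed; duplicates within one file are
#' collapsed, keeping the maximum relevance score where scores exist.
#'
#' @param path TSV file path.
#' @param source one of `"genecards"`, `"drugbank"`, `"pharmgkb"`,
#'   `"pubchem"`.
#' @return a `gene_catalog` (possibly empty, with a warning).
#' @export
read_source_table <- function(path, source = catalog_sources) {
  source <- match.arg(source)
  if (!file.exists(path)) stop(sprintf("source file not found: %s", path), call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- switch(source,
                 genecards = c("symbol", "relevance_score"),
                 drugbank = c("drug", "target"),
                 c("symbol"))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s) for source '%s': %s",
                 path, source, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning(sprintf("%s: empty %s table", path, source), call. = FALSE)
    return(new_catalog(character(0), numeric(0), list()))
  }
  sym <- normalize_symbols(if (source == "drugbank") df$target else df$symbol)
  score <- if (source == "genecards") as.numeric(df$relevance_score) else
    rep(NA_real_, length(sym))
  keep <- sym != ""
  sym <- sym[keep]; score <- score[keep]
  agg_score <- tapply(score, sym, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  syms <- sort(unique(sym))
  new_catalog(syms, as.numeric(agg_score[syms]),
              replicate(length(syms), source, simplify = FALSE))
}

#' Merge gene catalogs
#'
#' One record per symbol; source tags are unioned, and the relevance
#' score carried is the maximum over contributing records (scores are
#' "higher = stronger association", and max is order-free). Merging is
#' invariant to the order of the input catalogs and idempotent.
#'
#' @param catalogs a list of `gene_catalog` objects.
#' @return a merged `gene_catalog`, sorted by symbol.
#' @export
merge_catalogs <- function(catalogs) {
  stopifnot(is.list(catalogs), length(catalogs) >= 1L)
  sym <- unlist(lapply(catalogs, function(x) x$symbol), use.names = FALSE)
  score <- unlist(lapply(catalogs, function(x) x$relevance_score), use.names = FALSE)
  src <- do.call(c, lapply(catalogs, function(x) x$sources))
  syms <- sort(unique(sym))
  out_score <- vapply(syms, function(s) {
    v <- score[sym == s]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, 0)
  out_src <- lapply(syms, function(s) {
    sort(unique(unlist(src[sym == s], use.names = FALSE)))
  })
  new_catalog(syms, unname(out_score), out_src)
}

#' Intersect disease and compound target sets
#'
#' The Venn step: partitions the union of both inputs into
#' `disease_only`, `compound_only` and `common` (the shared targets that
#' form the analysis gene list when a compound table is supplied).
#'
#' @param disease character vector of disease gene symbols.
#' @param compound character vector of compound target symbols.
#' @return an object of class `target_intersection` with the three
#'   disjoint sets.
#' @export
intersect_targets <- function(disease, compound) {
  disease <- unique(normalize_symbols(disease))
  compound <- unique(normalize_symbols(compound))
  out <- structure(list(
    disease_only = sort(setdiff(disease, compound)),
    compound_only = sort(setdiff(compound, disease)),
    common = sort(intersect(disease, compound))
  ), class = "target_intersection")
  np_log("target intersection: %d disease-only, %d common, %d compound-only",
         length(out$disease_only), length(out$common), length(out$compound_only))
  out
}

#' @export
print.target_intersection <- function(x, ...) {
  cat(sprintf("<target_intersection> disease-only %d | common %d | compound-only %d\n",
              length(x$disease_only), length(x$common), length(x$compound_only)))
  invisible(x)
}

#' Write a merged catalog as TSV
#'
#' @param catalog a `gene_catalog`.
#' @param path output path; the `sources` list column is flattened with
#'   `;` separators.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  flat <- data.frame(
    symbol = catalog$symbol,
    relevance_score = catalog$relevance_score,
    sources = vapply(catalog$sources, paste, "", collapse = ";")
  )
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
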