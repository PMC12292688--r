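#' Critical-subnetwork extraction by iterated median filtering
#'
#' The core subnetwork is obtained by repeatedly keeping only nodes whose
#' centrality exceeds the current graph's median on every metric of a
#' configured panel (by default the five-measure panel: degree,
#' betweenness, closeness, eigenvector, LAC), recomputing centralities
#' and medians on the surviving induced subgraph between rounds.
#' Recomputation each round is what makes a second identical filtering
#' pass narrow the network further.
#'
#' @name core_extraction
NULL

core_metrics_all <- c("degree", "betweenness", "closeness", "eigenvector", "lac")

#' Core-extraction configuration
#'
#' @param metrics ordered subset of
#'   `c("degree","betweenness","closeness","eigenvector","lac")`.
#' @param rounds number of filtering rounds (default 2).
#' @param comparison `"strict"` keeps values strictly above the median
#'   ("a higher score than the median"); `"inclusive"` keeps ties with it,
#'   a fallback for degenerate graphs where every node ties.
#' @param combine `"all"` requires a node to pass every metric
#'   (conjunction, the default); `"any"` keeps a node passing at least one
#'   metric, for sensitivity analysis.
#' @return an object of class `core_config`.
#' @export
core_config <- function(metrics = core_metrics_all, rounds = 2L,
                        comparison = c("strict", "inclusive"),
                        combine = c("all", "any")) {
  comparison <- match.arg(comparison)
  combine <- match.arg(combine)
  metrics <- match.arg(metrics, core_metrics_all, several.ok = TRUE)
  rounds <- as.integer(rounds)
  if (length(metrics) == 0L) stop("`metrics` must be nonempty", call. = FALSE)
  if (is.na(rounds) || rounds < 1L) stop("`rounds` must be >= 1", call. = FALSE)
  structure(list(metrics = metrics, rounds = rounds,
                 comparison = comparison, combine = combine),
            class = "core_config")
}

#' One median-filter round
#'
#' Keeps nodes whose centrality exceeds (or, under `"inclusive"`, reaches)
#' the median of the current graph's values, for every metric of the
#' panel, and returns the induced subgraph. The medians applied are
#' attached as the `"medians"` attribute, and a per-metric report as the
#' `"report"` attribute.
#'
#' @param g a `ppi_graph`.
#' @param profiles optional precomputed [profile_all()] table covering
#'   exactly the nodes of `g`; computed if `NULL`.
#' @param cfg a [core_config()].
#' @return the filtered `ppi_graph`.
#' @export
median_filter_round <- function(g, profiles = NULL, cfg = core_config()) {
  stopifnot(inherits(cfg, "core_config"))
  nodes <- graph_nodes(g)
  if (length(nodes) == 0L) stop("cannot filter an empty graph", call. = FALSE)
  if (is.null(profiles)) profiles <- profile_all(g)
  if (!setequal(profiles$node, nodes)) {
    stop("`profiles` must cover exactly the nodes of `g`", call. = FALSE)
  }
  profiles <- profiles[match(nodes, profiles$node), , drop = FALSE]
  pass <- if (cfg$combine == "all") rep(TRUE, length(nodes)) else
    rep(FALSE, length(nodes))
  medians <- setNames(numeric(length(cfg$metrics)), cfg$metrics)
  report <- data.frame(metric = cfg$metrics, median = NA_real_,
                       passing = NA_integer_)
  for (i in seq_along(cfg$metrics)) {
    m <- cfg$metrics[i]
    vals <- profiles[[m]]
    med <- median(vals)
    medians[m] <- med
    ok <- if (cfg$comparison == "strict") vals > med else vals >= med
    report$median[i] <- med
    report$passing[i] <- sum(ok)
    before_empty <- !any(pass)
    pass <- if (cfg$combine == "all") pass & ok else pass | ok
    if (cfg$combine == "all" && !any(pass) && !before_empty) {
      stop(sprintf("median filter on metric '%s' (median %.6g) left no nodes",
                   m, med), call. = FALSE)
    }
  }
  if (!any(pass)) {
    stop(sprintf("median filter on metric '%s' (median %.6g) left no nodes",
                 cfg$metrics[1], medians[1]), call. = FALSE)
  }
  out <- induced_ppi(g, nodes[pass])
  attr(out, "medians") <- medians
  attr(out, "report") <- report
  out
}

#' Extract the critical subnetwork
#'
#' Applies [median_filter_round()] `cfg$rounds` times, recomputing the
#' centrality profiles and medians on each surviving subgraph. A round
#' that would empty the graph aborts with the round index. The per-round
#' node counts and medians are attached as the `"report"` attribute
#' (columns `round`, `metric`, `median`, `nodes_before`, `nodes_after`).
#'
#' @param g a `ppi_graph`.
#' @param cfg a [core_config()].
#' @return the core `ppi_graph` with a `"report"` attribute.
#' @export
extract_core <- function(g, cfg = core_config()) {
  stopifnot(inherits(cfg, "core_config"))
  cur <- g
  rows <- list()
  for (r in seq_len(cfg$rounds)) {
    n_before <- length(graph_nodes(cur))
    nxt <- tryCatch(
      median_filter_round(cur, profiles = NULL, cfg = cfg),
      error = function(e) {
        stop(sprintf("core extraction failed at round %d: %s", r,
                     conditionMessage(e)), call. = FALSE)
      }
    )
    rep_r <- attr(nxt, "report")
    rep_r$round <- r
    rep_r$nodes_before <- n_before
    rep_r$nodes_after <- length(graph_nodes(nxt))
    rows[[r]] <- rep_r[, c("round", "metric", "median",
                           "nodes_before", "nodes_after")]
    cur <- nxt
  }
  attr(cur, "report") <- do.call(rbind, rows)
  attr(cur, "medians") <- NULL
  cur
}
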