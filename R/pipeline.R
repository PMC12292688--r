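#' End-to-end pipeline
#'
#' One entry point running the whole workflow: read and merge the source
#' gene tables, intersect disease and compound targets, build the
#' confidence-filtered PPI network over the analysis list, profile all
#' centralities, extract the median-filtered core, rank hub genes by
#' degree and MCC on the full network, and run pathway
#' over-representation analysis — writing every intermediate artifact and
#' a JSON manifest into the output directory.
#'
#' @name pipeline_cli
NULL

config_defaults <- list(
  confidence = 0.400,
  keep_isolates = FALSE,
  lcc_only = FALSE,
  core = list(metrics = core_metrics_all, rounds = 2L, comparison = "strict"),
  hubs = list(methods = c("degree", "mcc"), k = 10L, consensus = "intersection"),
  enrichment = list(background = NULL, min_overlap = 2L),
  seed = 1L,
  log_level = "INFO"
)

known_keys <- list(
  top = c("inputs", "confidence", "keep_isolates", "lcc_only", "core",
          "hubs", "enrichment", "outdir", "seed", "log_level"),
  inputs = c("genecards", "drugbank", "pharmgkb", "pubchem", "edges", "gmt"),
  core = c("metrics", "rounds", "comparison"),
  hubs = c("methods", "k", "consensus"),
  enrichment = c("background", "min_overlap")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop(sprintf("unknown config key '%s' in %s", extra[1], where), call. = FALSE)
  }
}

#' Validate a pipeline configuration file
#'
#' The configuration is a JSON object. Required: `inputs` with paths for
#' `genecards` and `edges` (optional: `drugbank`, `pharmgkb`, `pubchem`,
#' `gmt`) and `outdir`. All other keys receive documented defaults
#' (confidence 0.400, two strict filtering rounds over the five-metric
#' panel, top-10 degree/MCC hubs with intersection consensus, ORA
#' min_overlap 2). Unknown keys and out-of-range values are rejected with
#' the offending key named.
#'
#' @param path path to the JSON config file.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(raw, known_keys$top, "config")
  if (is.null(raw$inputs)) stop("config is missing 'inputs'", call. = FALSE)
  check_keys(raw$inputs, known_keys$inputs, "inputs")
  for (key in c("genecards", "edges")) {
    if (is.null(raw$inputs[[key]])) {
      stop(sprintf("config is missing required input path '%s'", key), call. = FALSE)
    }
  }
  if (is.null(raw$outdir)) stop("config is missing 'outdir'", call. = FALSE)
  cfg <- utils::modifyList(config_defaults, raw)
  for (sec in c("core", "hubs", "enrichment")) {
    check_keys(cfg[[sec]], known_keys[[sec]], sec)
    cfg[[sec]] <- utils::modifyList(config_defaults[[sec]],
                                    cfg[[sec]] %||% list())
  }
  for (key in setdiff(known_keys$inputs, "background")) {
    pth <- cfg$inputs[[key]]
    if (!is.null(pth) && !file.exists(pth)) {
      stop(sprintf("input '%s' does not exist: %s", key, pth), call. = FALSE)
    }
  }
  assert_scalar_number(cfg$confidence, "confidence", 0, 1)
  if (cfg$core$rounds < 1) stop("'core.rounds' must be >= 1", call. = FALSE)
  if (!all(cfg$core$metrics %in% core_metrics_all)) {
    stop("'core.metrics' must be a subset of the five-metric panel", call. = FALSE)
  }
  if (!cfg$core$comparison %in% c("strict", "inclusive")) {
    stop("'core.comparison' must be 'strict' or 'inclusive'", call. = FALSE)
  }
  if (cfg$hubs$k < 1) stop("'hubs.k' must be >= 1", call. = FALSE)
  if (!all(cfg$hubs$methods %in% c("degree", "mcc"))) {
    stop("'hubs.methods' must be among 'degree', 'mcc'", call. = FALSE)
  }
  if (!cfg$hubs$consensus %in% c("intersection", "union")) {
    stop("'hubs.consensus' must be 'intersection' or 'union'", call. = FALSE)
  }
  if (cfg$enrichment$min_overlap < 0) {
    stop("'enrichment.min_overlap' must be >= 0", call. = FALSE)
  }
  bg <- cfg$enrichment$background
  if (!is.null(bg) && !file.exists(bg)) {
    stop(sprintf("input 'background' does not exist: %s", bg), call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline
#'
#' @param config a `run_config` from [validate_config()] or the path to a
#'   JSON config file.
#' @return the run manifest (a list, also written as `manifest.json` in
#'   the output directory), invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  outdir <- cfg$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  art <- function(f) file.path(outdir, f)
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "inputs")],
    inputs = lapply(Filter(Negate(is.null), cfg$inputs),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    stages = list(),
    notes = "experimental verification stage: out of scope"
  )

  # 1. gene catalog
  disease_tables <- list(read_source_table(cfg$inputs$genecards, "genecards"))
  for (src in c("pharmgkb", "pubchem")) {
    if (!is.null(cfg$inputs[[src]])) {
      disease_tables <- c(disease_tables,
                          list(read_source_table(cfg$inputs[[src]], src)))
    }
  }
  disease_catalog <- merge_catalogs(disease_tables)
  compound_catalog <- if (!is.null(cfg$inputs$drugbank)) {
    read_source_table(cfg$inputs$drugbank, "drugbank")
  } else NULL
  write_catalog(disease_catalog, art("disease_catalog.tsv"))
  if (!is.null(compound_catalog)) {
    inter <- intersect_targets(disease_catalog$symbol, compound_catalog$symbol)
    analysis_list <- inter$common
    jsonlite::write_json(unclass(inter), art("target_intersection.json"),
                         auto_unbox = FALSE, pretty = TRUE)
  } else {
    inter <- NULL
    analysis_list <- disease_catalog$symbol
  }
  manifest$stages$gene_catalog <- list(
    disease_genes = nrow(disease_catalog),
    compound_targets = if (is.null(compound_catalog)) 0L else nrow(compound_catalog),
    analysis_list = length(analysis_list)
  )

  # 2. PPI network
  edges <- read_string_edges(cfg$inputs$edges)
  g <- build_graph(edges, analysis_list, threshold = cfg$confidence,
                   keep_isolates = cfg$keep_isolates, lcc_only = cfg$lcc_only,
                   source = cfg$inputs$edges)
  export_graph(g, art("network.tsv"), format = "edge-tsv")
  export_graph(g, art("network.graphml"), format = "graphml")
  manifest$stages$ppi_graph <- list(nodes = length(graph_nodes(g)),
                                    edges = nrow(graph_edges(g)),
                                    threshold = cfg$confidence)

  # 3. centralities on the full network
  profiles <- profile_all(g)
  write_profiles(profiles, art("centrality.tsv"))
  manifest$stages$centrality <- list(nodes = nrow(profiles))

  # 4. core extraction
  core_cfg <- core_config(metrics = cfg$core$metrics,
                          rounds = cfg$core$rounds,
                          comparison = cfg$core$comparison)
  core <- extract_core(g, core_cfg)
  export_graph(core, art("core_network.tsv"), format = "edge-tsv")
  write.table(attr(core, "report"), art("core_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest$stages$core_extraction <- list(
    nodes = length(graph_nodes(core)),
    rounds = cfg$core$rounds
  )

  # 5. hub ranking on the full (unfiltered) network
  rankings <- list()
  for (mth in cfg$hubs$methods) {
    rk <- rank_hubs(g, method = mth, k = cfg$hubs$k)
    rankings[[mth]] <- rk
    write_hub_ranking(rk, art(sprintf("hubs_%s.tsv", mth)))
  }
  hubs <- if (length(rankings) == 2L) {
    consensus_hubs(rankings[[1]], rankings[[2]], rule = cfg$hubs$consensus)
  } else {
    sort(rankings[[1]]$symbol)
  }
  writeLines(hubs, art("hub_consensus.txt"))
  sub <- hub_subnetwork(g, hubs)
  export_graph(sub, art("hub_subnetwork.tsv"), format = "edge-tsv")
  manifest$stages$hub_ranking <- list(methods = cfg$hubs$methods,
                                      k = cfg$hubs$k,
                                      consensus_hubs = hubs)

  # 6. enrichment
  if (!is.null(cfg$inputs$gmt)) {
    pw <- read_gmt(cfg$inputs$gmt)
    bg <- if (!is.null(cfg$enrichment$background)) {
      normalize_symbols(readLines(cfg$enrichment$background, warn = FALSE))
    } else NULL
    ora <- run_ora(intersect(analysis_list,
                             if (is.null(bg)) unique(unlist(pw)) else bg),
                   pw, background = bg,
                   min_overlap = cfg$enrichment$min_overlap)
    export_enrichment(ora, art("enrichment.tsv"))
    manifest$stages$enrichment <- list(pathways_tested = length(pw),
                                       rows_reported = nrow(ora))
  } else {
    manifest$stages$enrichment <- list(skipped = "no GMT input configured")
  }

  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  np_log("pipeline complete: artifacts in %s", outdir)
  invisible(manifest)
}
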