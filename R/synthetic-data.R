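#' Synthetic network-pharmacology scenarios
#'
#' Offline stand-ins for the external databases a network-pharmacology
#' study would query: a scored disease-gene table, drug-target and
#' pharmacogene tables, a STRING-style interaction edge list over the
#' disease/compound gene intersection with planted high-connectivity hubs,
#' and a GMT pathway collection with planted enrichment — together with
#' the ground truth (`planted_hubs`, `planted_enriched_pathways`) needed
#' for recovery tests.
#'
#' @name synthetic_data
NULL

# Preferential-attachment edge generator with a planted rich-club.
#
# The first `n_hubs` nodes start as a clique, and every later node attaches
# m = 2 edges: the first by degree-proportional (Barabasi-Albert style)
# preferential attachment, the second closing a triangle on a uniformly
# chosen neighbor of the first target with probability `p_triad`, else by
# preferential attachment again. The hub clique plus triad closure gives
# the dense local neighborhoods (high LAC around hubs) that real PPI
# modules show and that pure m = 2 preferential attachment lacks.
pa_edges <- function(nodes, n_hubs, m = 2L, p_triad = 0.9) {
  n <- length(nodes)
  stopifnot(n >= 2L)
  seed_k <- max(2L, min(n_hubs, n))
  edges_a <- integer(0)
  edges_b <- integer(0)
  adj <- vector("list", n)
  add_edge <- function(i, j) {
    edges_a <<- c(edges_a, i); edges_b <<- c(edges_b, j)
    adj[[i]] <<- c(adj[[i]], j); adj[[j]] <<- c(adj[[j]], i)
  }
  for (i in seq_len(seed_k - 1L)) for (j in seq(i + 1L, seed_k)) add_edge(i, j)
  # multiset of endpoints: sampling from it is degree-proportional
  repeated <- c(edges_a, edges_b)
  for (new in seq_len(n)[-seq_len(seed_k)]) {
    mm <- min(m, new - 1L)
    targets <- integer(0)
    while (length(targets) < mm) {
      t1 <- repeated[sample.int(length(repeated), 1L)]
      if (t1 %in% targets) next
      targets <- c(targets, t1)
      while (length(targets) < mm && stats::runif(1) < p_triad) {
        nbrs <- setdiff(adj[[t1]], targets)
        if (length(nbrs) == 0L) break
        targets <- c(targets, nbrs[sample.int(length(nbrs), 1L)])
      }
    }
    for (t in targets) {
      add_edge(new, t)
      repeated <- c(repeated, new, t)
    }
  }
  data.frame(a = nodes[edges_a], b = nodes[edges_b])
}

#' Generate a complete synthetic scenario
#'
#' All randomness derives from the single `seed`; the global RNG state is
#' left untouched. Default sizes emulate a small disease study: a ~120-gene
#' scored disease list, 90 compound targets sharing most of the disease
#' list, a scale-free interaction network over the shared genes with
#' `n_hubs` planted hubs (the earliest, highest-degree positions of the
#' attachment process), and a pathway collection in which 25% of pathways
#' are planted enriched: a fraction `enrichment_effect` of each planted
#' pathway's members is drawn from the analysis gene list and the remainder
#' uniformly from the rest of the background, so setting the effect equal
#' to the list's background fraction yields a calibrated null.
#'
#' True interactions receive combined scores uniform on 401..999; an equal
#' number of decoy non-edges receive scores 1..399, so the default 0.400
#' confidence threshold separates them exactly.
#'
#' @param n_bg background universe size.
#' @param n_dis number of scored disease genes.
#' @param n_cmp number of compound target genes.
#' @param n_hubs number of planted hubs.
#' @param n_pathways number of pathways in the GMT collection.
#' @param enrichment_effect fraction of each planted pathway drawn from
#'   the analysis list, in `(0, 1]`.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_scenario`.
#' @export
generate_scenario <- function(n_bg = 1000L, n_dis = 120L, n_cmp = 90L,
                              n_hubs = 5L, n_pathways = 20L,
                              enrichment_effect = 0.5, seed = 1L) {
  n_bg <- as.integer(n_bg); n_dis <- as.integer(n_dis)
  n_cmp <- as.integer(n_cmp); n_hubs <- as.integer(n_hubs)
  n_pathways <- as.integer(n_pathways)
  if (n_bg < n_dis + n_cmp) {
    stop("infeasible sizes: need n_bg >= n_dis + n_cmp", call. = FALSE)
  }
  if (n_hubs > min(n_dis, n_cmp)) {
    stop("infeasible sizes: need n_hubs <= min(n_dis, n_cmp)", call. = FALSE)
  }
  if (!is.numeric(enrichment_effect) || enrichment_effect <= 0 ||
      enrichment_effect > 1) {
    stop("`enrichment_effect` must be in (0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    universe <- sprintf("GENE%04d", seq_len(n_bg))
    disease <- sample(universe, n_dis)
    # relevance scores: lognormal, heavy right tail like curated
    # disease-association scores; 2 decimal places
    scores <- round(exp(rnorm(n_dis, mean = log(8), sd = 0.7)), 2)
    # compound targets: most are shared with the disease list (the
    # analysis list is their intersection), a handful are compound-only
    n_outside <- min(5L, n_cmp - n_hubs, n_bg - n_dis)
    n_shared <- n_cmp - n_outside
    if (n_shared > n_dis) {
      n_outside <- n_cmp - n_dis
      n_shared <- n_dis
    }
    shared <- sample(disease, n_shared)
    hubs <- shared[seq_len(n_hubs)]
    outside <- if (n_outside > 0L)
      sample(setdiff(universe, disease), n_outside) else character(0)
    compound <- c(shared, outside)

    true_edges <- pa_edges(shared, n_hubs = n_hubs, m = 2L, p_triad = 0.9)
    n_true <- nrow(true_edges)
    true_key <- paste(pmin(true_edges$a, true_edges$b),
                      pmax(true_edges$a, true_edges$b), sep = "\t")
    # decoy edges at ratio 1:1, scored below the 0.400 threshold
    decoy_a <- character(0); decoy_b <- character(0)
    seen <- true_key
    guard <- 0L
    while (length(decoy_a) < n_true && guard < 50L * n_true) {
      guard <- guard + 1L
      pair <- sample(shared, 2L)
      key <- paste(min(pair), max(pair), sep = "\t")
      if (key %in% seen) next
      seen <- c(seen, key)
      decoy_a <- c(decoy_a, pair[1]); decoy_b <- c(decoy_b, pair[2])
    }
    edges <- data.frame(
      protein1 = c(true_edges$a, decoy_a),
      protein2 = c(true_edges$b, decoy_b),
      combined_score = c(sample(401:999, n_true, replace = TRUE),
                         sample(1:399, length(decoy_a), replace = TRUE))
    )

    n_planted <- max(1L, round(0.25 * n_pathways))
    pw_ids <- sprintf("PW%03d", seq_len(n_pathways))
    planted_ids <- pw_ids[seq_len(n_planted)]
    analysis_list <- shared
    rest_bg <- setdiff(universe, analysis_list)
    pathways <- vector("list", n_pathways)
    names(pathways) <- pw_ids
    for (i in seq_len(n_pathways)) {
      size <- sample(20:80, 1L)
      if (i <= n_planted) {
        n_in <- min(max(1L, round(enrichment_effect * size)),
                    length(analysis_list))
        members <- c(sample(analysis_list, n_in),
                     sample(rest_bg, size - n_in))
      } else {
        members <- sample(universe, size)
      }
      pathways[[i]] <- sort(members)
    }

    # source-table memberships (fixed here so writing needs no RNG)
    pharmgkb <- sort(sample(disease, max(1L, round(0.3 * n_dis))))
    pubchem <- sort(sample(disease, max(1L, round(0.2 * n_dis))))
    drug_pool <- sprintf("DRUG%02d", seq_len(max(3L, ceiling(n_cmp / 10))))
    drug_map <- data.frame(
      drug = sample(drug_pool, n_cmp, replace = TRUE),
      target = compound
    )

    structure(list(
      universe = universe,
      disease_genes = data.frame(symbol = disease, relevance_score = scores),
      compound_targets = compound,
      edges = edges,
      pathways = pathways,
      pathway_names = setNames(sprintf("Synthetic pathway %d", seq_len(n_pathways)),
                               pw_ids),
      planted_hubs = hubs,
      planted_enriched_pathways = planted_ids,
      pharmgkb_genes = pharmgkb,
      pubchem_genes = pubchem,
      drug_map = drug_map,
      params = list(n_bg = n_bg, n_dis = n_dis, n_cmp = n_cmp,
                    n_hubs = n_hubs, n_pathways = n_pathways,
                    enrichment_effect = enrichment_effect, seed = seed)
    ), class = "synthetic_scenario")
  })
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scenario> seed %d: %d background genes, ",
                     "%d disease genes, %d compound targets, %d edges, ",
                     "%d pathways (%d planted), %d planted hubs\n"),
              x$params$seed, length(x$universe), nrow(x$disease_genes),
              length(x$compound_targets), nrow(x$edges),
              length(x$pathways), length(x$planted_enriched_pathways),
              length(x$planted_hubs)))
  invisible(x)
}

#' Write a scenario to disk as its seven source files
#'
#' Emits `genecards.tsv` (symbol, relevance_score), `drugbank.tsv`
#' (drug, target), `pharmgkb.tsv` (symbol), `pubchem.tsv` (symbol),
#' `string_edges.tsv` (protein1, protein2, combined_score),
#' `pathways.gmt`, and `truth.json` holding the planted structure.
#' Writing uses no randomness, so the same scenario always produces
#' byte-identical files.
#'
#' @param s a `synthetic_scenario`.
#' @param directory output directory (created if missing).
#' @return named character vector of the seven file paths (the manifest).
#' @export
write_scenario <- function(s, directory) {
  stopifnot(inherits(s, "synthetic_scenario"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", directory), call. = FALSE)
  }
  p <- function(f) file.path(directory, f)
  tsv <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(s$disease_genes, "genecards.tsv")
  tsv(s$drug_map, "drugbank.tsv")
  tsv(data.frame(symbol = s$pharmgkb_genes), "pharmgkb.tsv")
  tsv(data.frame(symbol = s$pubchem_genes), "pubchem.tsv")
  tsv(s$edges, "string_edges.tsv")
  gmt_lines <- vapply(names(s$pathways), function(id) {
    paste(c(id, unname(s$pathway_names[id]), s$pathways[[id]]),
          collapse = "\t")
  }, "")
  writeLines(gmt_lines, p("pathways.gmt"))
  jsonlite::write_json(
    list(planted_hubs = s$planted_hubs,
         planted_enriched_pathways = s$planted_enriched_pathways,
         params = s$params),
    p("truth.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  files <- c(genecards = p("genecards.tsv"), drugbank = p("drugbank.tsv"),
             pharmgkb = p("pharmgkb.tsv"), pubchem = p("pubchem.tsv"),
             edges = p("string_edges.tsv"), gmt = p("pathways.gmt"),
             truth = p("truth.json"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop(sprintf("failed to write: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  files
}
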