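#' Assign semantic IC1/IC2 names to two clusters
#'
#' The integrative-cluster names are semantic, not algorithmic: IC1 is the
#' cluster with the higher mean enrichment of mitochondrial / oxidative-
#' phosphorylation gene sets when an enrichment matrix is available, and
#' otherwise the cluster containing the lexicographically smallest sample
#' name (a deterministic anchor).
#'
#' @param labels named integer/character cluster labels (two clusters).
#' @param es optional enrichment matrix (gene sets x samples).
#' @param pattern regular expression selecting the anchoring gene sets in
#'   `rownames(es)`.
#' @return A named character vector with values `"IC1"` / `"IC2"`, plus an
#'   attribute `anchor` saying which rule fixed the orientation.
#' @export
assign_ic_names <- function(labels, es = NULL,
                            pattern = "MITO|OXID|OXPHOS") {
  cl <- as.character(labels)
  names(cl) <- names(labels)
  clusters <- sort(unique(cl))
  if (length(clusters) != 2L) stop("expected exactly two clusters")
  anchor <- "lexicographic"
  ic1 <- clusters[vapply(clusters, function(g) min(names(cl)) %in% names(cl)[cl == g],
                         logical(1))]
  if (!is.null(es)) {
    hits <- grep(pattern, rownames(es), ignore.case = TRUE, value = TRUE)
    shared <- intersect(names(cl), colnames(es))
    if (length(hits) && length(shared)) {
      means <- vapply(clusters, function(g) {
        mean(es[hits, intersect(shared, names(cl)[cl == g]), drop = FALSE])
      }, numeric(1))
      ic1 <- clusters[which.max(means)]
      anchor <- "enrichment"
    }
  }
  out <- ifelse(cl == ic1, "IC1", "IC2")
  names(out) <- names(cl)
  attr(out, "anchor") <- anchor
  out
}

#' Run the full integrative-clustering pipeline
#'
#' Chains the stages on paired inputs: aberration burden profiling, driver
#' selection, consensus clustering of the expression samples on the selected
#' driver genes, IC1/IC2 naming, SAM subtype signature on the driver genes,
#' ssGSEA scoring with rank normalization and subtype-specific pathway
#' calls, and per-drug IC50 comparison between the clusters. Running the
#' stages separately with the same seed gives identical results; the
#' effective configuration is echoed in the returned object (and to the log).
#'
#' @param calls a [cn_calls] object.
#' @param expr numeric expression matrix (genes x samples); its sample set
#'   may exceed that of `calls` (clustering uses all expression samples,
#'   driver selection the shared ones).
#' @param gene_sets a [gene_set_collection] (or `NULL` to skip enrichment).
#' @param ic50 an [ic50_table] (or `NULL` to skip drug comparisons).
#' @param config a [pipeline_config].
#' @param out_dir optional directory; when given, every stage's files are
#'   written there.
#' @param k_range candidate cluster numbers for the stability statistics;
#'   the labels used downstream are taken at `config$n_clusters`.
#' @param verbose emit per-stage timing messages.
#' @return A list with elements `burden`, `drivers`, `driver_genes`,
#'   `consensus`, `k_advice`, `labels` (IC1/IC2 per expression sample),
#'   `sam`, `signature`, `centroids`, `enrichment` (normalized), `pathways`,
#'   `drug_comparisons`, `config`.
#' @export
run_pipeline <- function(calls, expr, gene_sets = NULL, ic50 = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         k_range = NULL, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    if (verbose) message(sprintf("[%6.1fs] ", proc.time()[["elapsed"]] - t0),
                         sprintf(fmt, ...))
  }
  expr <- expression_matrix(expr)
  if (is.null(k_range)) {
    k_range <- seq(2L, min(5L, ncol(expr) - 1L))
  }
  if (!config$n_clusters %in% k_range) {
    k_range <- sort(unique(c(k_range, config$n_clusters)))
  }
  say("config: %s", paste(names(config), vapply(config, function(v)
    paste(utils::head(v, 3), collapse = ","), character(1)),
    sep = "=", collapse = " "))

  burden <- count_aberrations(calls)
  say("aberration burden for %d samples", nrow(burden))

  drivers <- select_drivers(calls, expr, config)
  driver_genes <- drivers$gene[drivers$selected]
  say("driver selection: %d of %d testable genes selected",
      length(driver_genes), sum(drivers$reason == "ok"))
  if (length(driver_genes) < 3L) {
    stop("fewer than 3 driver genes selected; cannot cluster")
  }

  consensus <- consensus_cluster(expr, driver_genes, k_range = k_range,
                                 config = config)
  k_advice <- select_k(consensus$per_k_stats)
  raw_labels <- consensus$labels[[as.character(config$n_clusters)]]
  say("consensus clustering done (k used = %d, advisory k = %d)",
      config$n_clusters, k_advice$k)

  enrichment <- NULL
  pathways <- NULL
  if (!is.null(gene_sets) && length(gene_sets)) {
    enrichment <- rank_normalize(
      ssgsea_matrix(expr, gene_sets, alpha = config$ssgsea_alpha))
    say("ssGSEA scored %d sets x %d samples", nrow(enrichment), ncol(enrichment))
  }
  labels <- assign_ic_names(raw_labels, es = enrichment)
  say("cluster naming anchored by %s rule", attr(labels, "anchor"))

  sam <- sam_analysis(expr[intersect(driver_genes, rownames(expr)), ,
                           drop = FALSE],
                      labels, config = config)
  signature <- select_signature(sam, config$signature_q_threshold)
  centroids <- if (nrow(signature)) {
    signature_centroids(expr, labels, signature$feature)
  } else NULL
  say("SAM signature: %d features at q < %g", nrow(signature),
      config$signature_q_threshold)

  if (!is.null(enrichment)) {
    pathways <- subtype_pathways(enrichment, labels, config = config)
    say("subtype pathways: %d UP, %d DOWN", sum(pathways$call == "UP"),
        sum(pathways$call == "DOWN"))
  }

  drug_comparisons <- NULL
  if (!is.null(ic50)) {
    drug_comparisons <- compare_all_drugs(ic50, labels,
                                          min_group_size = config$min_group_size)
    say("drug comparisons: %d drugs tested",
        sum(drug_comparisons$reason == ""))
  }

  result <- list(burden = burden, drivers = drivers,
                 driver_genes = driver_genes, consensus = consensus,
                 k_advice = k_advice, labels = labels, sam = sam,
                 signature = signature, centroids = centroids,
                 enrichment = enrichment, pathways = pathways,
                 drug_comparisons = drug_comparisons, config = config)
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write every stage's outputs
#'
#' @param result output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$burden, file.path(dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_driver_report(result$drivers, file.path(dir, "drivers.tsv"))
  write_consensus_result(result$consensus, file.path(dir, "consensus"))
  utils::write.table(data.frame(sample = names(result$labels),
                                cluster = as.character(result$labels)),
                     file.path(dir, "cluster_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$signature, file.path(dir, "signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$centroids)) {
    jsonlite::write_json(list(features = rownames(result$centroids),
                              classes = colnames(result$centroids),
                              values = unname(as.data.frame(result$centroids))),
                         file.path(dir, "centroids.json"), digits = NA)
  }
  if (!is.null(result$enrichment)) {
    es <- result$enrichment
    chr <- array(vapply(as.numeric(es), function(v) format(v, digits = 17),
                        character(1)),
                 dim = dim(es), dimnames = dimnames(es))
    write_tsv_matrix(chr, file.path(dir, "enrichment.tsv"),
                     id_header = "gene_set")
    utils::write.table(result$pathways, file.path(dir, "pathways.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$drug_comparisons)) {
    utils::write.table(result$drug_comparisons, file.path(dir, "drugs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    n_samples_calls = length(result$burden$sample),
    n_driver_genes = length(result$driver_genes),
    k_used = result$config$n_clusters,
    k_advice = result$k_advice$k,
    cluster_sizes = as.list(table(as.character(result$labels))),
    n_signature_features = nrow(result$signature),
    n_pathways_up = if (is.null(result$pathways)) NULL else sum(result$pathways$call == "UP"),
    n_pathways_down = if (is.null(result$pathways)) NULL else sum(result$pathways$call == "DOWN"),
    config = unclass(result$config))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
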