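#' Spearman distance between samples
#'
#' Pairwise distance `1 - rho` between sample expression profiles restricted
#' to a gene list, where rho is the Spearman rank correlation. Distances lie
#' in `[0, 2]`; identical rank profiles are at 0 and exactly reversed
#' profiles at 2.
#'
#' @param expr numeric expression matrix (genes x samples).
#' @param genes optional gene subset (>= 3 genes after restriction).
#' @return A symmetric samples x samples matrix with zero diagonal.
#' @export
spearman_distance_matrix <- function(expr, genes = NULL) {
  expr <- expression_matrix(expr)
  if (!is.null(genes)) {
    genes <- intersect(rownames(expr), genes)
    expr <- expr[genes, , drop = FALSE]
  }
  if (nrow(expr) < 3L) stop("need at least 3 genes for a rank-based distance")
  const <- apply(expr, 2L, function(p) stats::sd(p) == 0)
  if (any(const)) {
    stop("constant expression profile for sample(s): ",
         paste(colnames(expr)[const], collapse = ", "))
  }
  d <- 1 - stats::cor(expr, method = "spearman")
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering cut at k
#'
#' Agglomerative clustering with unweighted average linkage (UPGMA) on a
#' precomputed distance matrix, cut to exactly `k` groups.
#'
#' @param dist_matrix symmetric distance matrix (or `dist` object).
#' @param k number of clusters, `2 <= k <= n`.
#' @return Integer cluster labels in `1..k`, named by sample.
#' @export
average_linkage_cluster <- function(dist_matrix, k) {
  d <- stats::as.dist(dist_matrix)
  n <- attr(d, "Size")
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  if (k < 1L) stop("k must be at least 1")
  stats::cutree(stats::hclust(d, method = "average"), k = k)
}

#' Resampling-based consensus clustering
#'
#' Repeatedly subsamples the cohort, clusters each subsample (Spearman
#' distance, average linkage) at each candidate `k`, and records how often
#' two samples fall in the same cluster when drawn together. The consensus
#' matrix entry for a sample pair is its co-cluster count divided by its
#' co-sampling count. Final labels per `k` come from average-linkage
#' clustering of `1 - consensus`. Fully deterministic for a given seed.
#'
#' @param expr numeric expression matrix (genes x samples).
#' @param genes gene subset to cluster on (e.g. selected driver genes).
#' @param k_range integer vector of candidate cluster numbers.
#' @param config a [pipeline_config] supplying `consensus_n_resamples`,
#'   `consensus_subsample_fraction` and `rng_seed`.
#' @param seed overrides `config$rng_seed` when given.
#' @return An object of class `consensus_result`: list with
#'   `consensus` (named list of consensus matrices per k),
#'   `cosample_counts`, `labels` (named list of integer labels per k),
#'   `per_k_stats` (data.frame `k`, `auc` of the consensus CDF),
#'   `k_range`, `n_resamples`, `n_redraws`, `seed`.
#' @export
consensus_cluster <- function(expr, genes, k_range = 2:5,
                              config = pipeline_config(), seed = NULL) {
  expr <- expression_matrix(expr)
  if (is.null(seed)) seed <- config$rng_seed
  k_range <- sort(unique(as.integer(k_range)))
  n <- ncol(expr)
  if (any(k_range < 2L) || any(k_range > n)) stop("k_range must lie in [2, n_samples]")
  frac <- config$consensus_subsample_fraction
  B <- config$consensus_n_resamples
  m <- ceiling(frac * n)
  if (m < max(k_range)) stop("subsample size smaller than the largest k")
  samples <- colnames(expr)
  cocluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(cocluster) <- as.character(k_range)
  cosample <- matrix(0, n, n)
  n_redraws <- 0L
  set.seed(seed)
  for (b in seq_len(B)) {
    repeat {
      idx <- sort(sample.int(n, m))
      sub <- expr[, idx, drop = FALSE]
      ok <- tryCatch({
        d <- spearman_distance_matrix(sub, genes)
        TRUE
      }, error = function(e) FALSE)
      if (ok) break
      n_redraws <- n_redraws + 1L
    }
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cuts <- stats::cutree(hc, k = k_range)
    if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1L)
    cosample[idx, idx] <- cosample[idx, idx] + 1
    for (j in seq_along(k_range)) {
      conn <- outer(cuts[, j], cuts[, j], `==`)
      kk <- as.character(k_range[j])
      cocluster[[kk]][idx, idx] <- cocluster[[kk]][idx, idx] + conn
    }
  }
  consensus <- lapply(cocluster, function(cc) {
    cm <- ifelse(cosample > 0, cc / pmax(cosample, 1), 0)
    dimnames(cm) <- list(samples, samples)
    cm
  })
  labels <- lapply(seq_along(k_range), function(j) {
    average_linkage_cluster(1 - consensus[[j]], k_range[j])
  })
  names(labels) <- as.character(k_range)
  per_k_stats <- data.frame(
    k = k_range,
    auc = vapply(consensus, consensus_cdf_auc, numeric(1))
  )
  rownames(per_k_stats) <- NULL
  structure(list(consensus = consensus, cosample_counts = cosample,
                 labels = labels, per_k_stats = per_k_stats,
                 k_range = k_range, n_resamples = B,
                 n_redraws = n_redraws, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d samples, k in {%s}, %d resamples (seed %d)\n",
              nrow(x$cosample_counts), paste(x$k_range, collapse = ", "),
              x$n_resamples, x$seed))
  print(x$per_k_stats)
  invisible(x)
}

# Area under the empirical CDF of the off-diagonal consensus entries,
# over the [0, 1] consensus axis.
consensus_cdf_auc <- function(cm) {
  v <- cm[upper.tri(cm)]
  xs <- sort(unique(c(0, v, 1)))
  cdf <- vapply(xs, function(t) mean(v <= t), numeric(1))
  sum(diff(xs) * cdf[-length(xs)])
}

#' Choose the number of clusters from consensus stability
#'
#' Formalizes the usual visual judgement of consensus stability with the
#' relative change in the area under the consensus CDF: with `A(k)` the area
#' for candidate `k`, `Delta(k)` is `A(k_min)` for the smallest candidate and
#' `(A(k) - A(k-1)) / A(k-1)` afterwards. The true cluster number is where
#' the stability gain collapses, so the chosen `k` is the candidate after
#' which `Delta` falls the most (the elbow of the `Delta` curve; smallest k
#' on ties, and smallest candidate outright when all areas are identical).
#' The smallest k at which `Delta` dips below `delta_threshold` is also
#' reported (`k_flat`) as the conventional flattening point; it is advisory
#' because near-threshold noise makes it unstable at moderate sample sizes.
#' All statistics are returned so the choice can be overridden by
#' inspection, as is usual for consensus plots.
#'
#' @param per_k_stats data.frame with columns `k` and `auc` (as produced by
#'   [consensus_cluster()]), at least two candidate k values.
#' @param delta_threshold flattening cut-off used for `k_flat` (default 0.1).
#' @return A list with `k` (the selection), `k_flat` (smallest k with
#'   `Delta < delta_threshold`, `NA` if none), and `stats` (data.frame `k`,
#'   `auc`, `delta`).
#' @export
select_k <- function(per_k_stats, delta_threshold = 0.1) {
  stopifnot(all(c("k", "auc") %in% names(per_k_stats)), nrow(per_k_stats) >= 2L)
  df <- per_k_stats[order(per_k_stats$k), , drop = FALSE]
  K <- nrow(df)
  delta <- c(df$auc[1L],
             diff(df$auc) / pmax(df$auc[-K], .Machine$double.eps))
  df$delta <- delta
  flat <- which(delta < delta_threshold)
  k_flat <- if (length(flat)) df$k[min(flat)] else NA_integer_
  if (length(unique(df$auc)) == 1L) {
    return(list(k = df$k[1L], k_flat = k_flat, stats = df))
  }
  drops <- delta[-K] - delta[-1L]
  list(k = df$k[which.max(drops)], k_flat = k_flat, stats = df)
}

#' Write consensus-clustering outputs
#'
#' @param result a `consensus_result`.
#' @param dir output directory (created if needed). Writes one consensus
#'   matrix TSV per k, a labels TSV per k, and the per-k statistics as JSON.
#' @export
write_consensus_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (kk in names(result$consensus)) {
    cm <- result$consensus[[kk]]
    chr <- array(vapply(cm, function(v) format(v, digits = 17), character(1)),
                 dim = dim(cm), dimnames = dimnames(cm))
    write_tsv_matrix(chr, file.path(dir, sprintf("consensus_k%s.tsv", kk)),
                     id_header = "sample")
    lab <- result$labels[[kk]]
    utils::write.table(data.frame(sample = names(lab), cluster = lab),
                       file.path(dir, sprintf("labels_k%s.tsv", kk)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$per_k_stats,
                       file.path(dir, "per_k_stats.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
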