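#' Single-sample gene-set enrichment score
#'
#' Rank-based enrichment of one gene set in one sample. Genes are ordered by
#' decreasing expression (ties broken by gene ID so the score is
#' deterministic) and given descending ranks `r` (top gene gets `N`). Two
#' running sums are walked down the list: the in-set sum weighted by
#' `r^alpha` and the uniform out-of-set sum. The enrichment score is the sum
#' over all positions of their difference (the integrated, single-sample
#' variant, not the max-deviation statistic):
#' `ES = sum_i P_in(i) - P_out(i)`.
#' The score depends on the expression values only through their ranks.
#'
#' @param profile named numeric vector: one sample's expression over all
#'   genes.
#' @param gene_set character vector of member gene IDs; its intersection
#'   with the profile must be non-empty and a proper subset of the profile.
#' @param alpha rank weighting exponent (>= 0; 0.25 by default downstream).
#' @return The enrichment score (dimensionless).
#' @export
ssgsea_score <- function(profile, gene_set, alpha = 0.25) {
  if (is.null(names(profile))) stop("profile must be a named vector")
  genes <- names(profile)
  inset <- genes %in% gene_set
  n_in <- sum(inset)
  if (n_in == 0L) stop("gene set has no genes in common with the profile")
  if (n_in == length(genes)) stop("gene set covers every profile gene; out-of-set sum undefined")
  ord <- order(-profile, genes)
  in_ord <- inset[ord]
  N <- length(genes)
  r <- N - seq_len(N) + 1            # descending ranks, top gene = N
  w <- r^alpha * in_ord
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_ord) / (N - n_in)
  sum(p_in - p_out)
}

#' ssGSEA score matrix
#'
#' Scores every gene set in every sample. Each sample's gene ordering is
#' computed once and reused across sets.
#'
#' @param expr numeric expression matrix (genes x samples).
#' @param sets a [gene_set_collection].
#' @param alpha rank weighting exponent.
#' @return A gene sets x samples numeric matrix of class
#'   `enrichment_matrix`, with attributes `normalized = FALSE` and `alpha`.
#' @export
ssgsea_matrix <- function(expr, sets, alpha = 0.25) {
  expr <- expression_matrix(expr)
  stopifnot(inherits(sets, "gene_set_collection"), length(sets) > 0L)
  genes <- rownames(expr)
  N <- length(genes)
  r <- N - seq_len(N) + 1
  member <- lapply(sets, function(g) genes %in% g)
  es <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-expr[, j], genes)
    vapply(seq_along(sets), function(si) {
      in_ord <- member[[si]][ord]
      n_in <- sum(in_ord)
      if (n_in == 0L) {
        stop(sprintf("gene set '%s' has no genes in the expression matrix",
                     names(sets)[si]))
      }
      if (n_in == N) {
        stop(sprintf("gene set '%s' covers every gene", names(sets)[si]))
      }
      w <- r^alpha * in_ord
      sum(cumsum(w) / sum(w) - cumsum(!in_ord) / (N - n_in))
    }, numeric(1))
  }, numeric(length(sets)))
  es <- matrix(es, nrow = length(sets),
               dimnames = list(names(sets), colnames(expr)))
  structure(es, normalized = FALSE, alpha = alpha,
            class = c("enrichment_matrix", "matrix"))
}

#' Rank-normalize an enrichment matrix to [0, 1]
#'
#' Linear min-max rescaling using the global matrix minimum and maximum:
#' `x -> (x - min) / (max - min)`. Order-preserving; the extremes map to
#' exactly 0 and 1. A constant matrix has no defined rescaling.
#'
#' @param es an `enrichment_matrix` (or plain numeric matrix).
#' @return The rescaled matrix with attribute `normalized = TRUE`.
#' @export
rank_normalize <- function(es) {
  rng <- range(es)
  if (diff(rng) == 0) stop("cannot rank-normalize a constant matrix")
  out <- (es - rng[1L]) / diff(rng)
  structure(as.matrix(unclass(out)), dimnames = dimnames(es),
            normalized = TRUE, alpha = attr(es, "alpha"),
            class = c("enrichment_matrix", "matrix"))
}

#' Subtype-specific pathway calls
#'
#' Runs SAM on a (rank-normalized) pathway x sample enrichment matrix with
#' two-class sample labels and combines the permutation q-value with the
#' fold change of mean enrichment (class 1 over class 2, denominator floored
#' at 1e-6). A pathway is called `UP` (enriched in class 1) when
#' `q < pathway_q_threshold` and fold change exceeds `pathway_fc_up`,
#' `DOWN` when `q < pathway_q_threshold` and fold change is below
#' `pathway_fc_down`, otherwise `NONE`.
#'
#' @param es normalized `enrichment_matrix` (gene sets x samples).
#' @param labels two-class labels over the samples (>= 2 per class).
#' @param config a [pipeline_config].
#' @param seed overrides `config$rng_seed` when given.
#' @return A `data.frame` with columns `pathway`, `d`, `q`, `fold_change`,
#'   `call`.
#' @export
subtype_pathways <- function(es, labels, config = pipeline_config(),
                             seed = NULL) {
  if (!isTRUE(attr(es, "normalized"))) {
    stop("enrichment matrix must be rank-normalized first (see rank_normalize)")
  }
  m <- as.matrix(unclass(es))
  sam <- sam_analysis(m, labels, config = config, seed = seed)
  f <- factor(labels)
  m1 <- rowMeans(m[, f == levels(f)[1L], drop = FALSE])
  m2 <- rowMeans(m[, f == levels(f)[2L], drop = FALSE])
  fc <- m1 / pmax(m2, 1e-6)
  call <- ifelse(sam$q < config$pathway_q_threshold & fc > config$pathway_fc_up, "UP",
          ifelse(sam$q < config$pathway_q_threshold & fc < config$pathway_fc_down, "DOWN",
                 "NONE"))
  data.frame(pathway = rownames(m), d = sam$d, q = sam$q,
             fold_change = fc, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}
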