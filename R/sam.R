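#' SAM two-class d-statistic
#'
#' The significance-analysis-of-microarrays relative difference for an
#' unpaired two-class design: per feature,
#' `d = (mean1 - mean2) / (s + s0)` where `s` is the pooled scatter
#' `sqrt((1/n1 + 1/n2) * (SS1 + SS2) / (n1 + n2 - 2))` and `s0` is a small
#' positive fudge constant that damps features with tiny variance.
#'
#' @param values numeric feature x sample matrix.
#' @param labels two-class labels over the samples (each class >= 2 samples).
#'   Class 1 is the first level of `factor(labels)`.
#' @param s0 fudge constant (>= 0).
#' @return A list with numeric vectors `d`, `s`, `mean_diff` (class1 -
#'   class2) and `classes` (the two class names, in order).
#' @export
sam_statistic <- function(values, labels, s0 = 0) {
  values <- as.matrix(values)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must define exactly two classes")
  if (length(f) != ncol(values)) stop("one label per sample column required")
  n1 <- sum(f == levels(f)[1L]); n2 <- sum(f == levels(f)[2L])
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  x1 <- values[, f == levels(f)[1L], drop = FALSE]
  x2 <- values[, f == levels(f)[2L], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * (ss1 + ss2) / (n1 + n2 - 2))
  list(d = (m1 - m2) / (s + s0), s = s, mean_diff = m1 - m2,
       classes = levels(f))
}

#' Estimate the SAM fudge constant s0
#'
#' Searches candidate values of `s0` taken at quantiles of the per-feature
#' scatter distribution and returns the candidate that makes `|d|` most
#' uniform across the scatter range: features are binned into scatter-decile
#' windows and the coefficient of variation of the windows' median `|d|` is
#' minimized. Deterministic; returns 0 when all scatters are identical.
#'
#' @param values numeric feature x sample matrix (>= 10 features
#'   recommended).
#' @param labels two-class labels.
#' @param percentiles candidate quantiles in `[0, 1]` (default 0 to 1 in
#'   steps of 0.05).
#' @return The chosen `s0` (smallest candidate on ties).
#' @export
estimate_s0 <- function(values, labels, percentiles = seq(0, 1, by = 0.05)) {
  base <- sam_statistic(values, labels, s0 = 0)
  s <- base$s
  if (max(s) - min(s) < .Machine$double.eps^0.5) return(0)
  candidates <- unique(as.numeric(stats::quantile(s, percentiles)))
  breaks <- unique(stats::quantile(s, seq(0, 1, by = 0.1)))
  if (length(breaks) < 3L) return(0)
  window <- cut(s, breaks = breaks, include.lowest = TRUE)
  objective <- vapply(candidates, function(s0) {
    d <- base$mean_diff / (s + s0)
    med <- tapply(abs(d), window, stats::median)
    med <- med[!is.na(med)]
    if (mean(med) == 0) return(Inf)
    stats::sd(med) / mean(med)
  }, numeric(1))
  candidates[which.min(objective)]
}

#' SAM permutation q-values
#'
#' False-discovery q-values for the SAM d-statistic by permutation of the
#' class labels. All distinct label assignments are enumerated when there are
#' at most `n_permutations` of them; otherwise that many distinct assignments
#' are drawn uniformly without replacement. For every threshold equal to an
#' observed `|d|`, the estimated FDR is the median permutation count of
#' features exceeding the threshold divided by the observed count; a
#' feature's q is the minimum FDR over all thresholds at or below its `|d|`,
#' capped at 1 (hence monotone non-increasing in `|d|`).
#'
#' @param values numeric feature x sample matrix.
#' @param labels two-class labels.
#' @param s0 fudge constant (see [estimate_s0()]).
#' @param n_permutations maximum number of label permutations (>= 100
#'   recommended).
#' @param seed integer seed (only used when sampling permutations).
#' @return A list with `q` (per-feature q-values), `d`, `s`,
#'   `n_permutations_used`, and `exhaustive` (whether all assignments were
#'   enumerated).
#' @export
sam_qvalues <- function(values, labels, s0 = 0, n_permutations = 1000L,
                        seed = 1L) {
  values <- as.matrix(values)
  obs <- sam_statistic(values, labels, s0 = s0)
  f <- factor(labels)
  n <- length(f); n1 <- sum(f == levels(f)[1L]); n2 <- n - n1
  total <- choose(n, n1)
  if (total <= n_permutations) {
    sets <- utils::combn(n, n1, simplify = FALSE)
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    seen <- new.env(hash = TRUE)
    sets <- vector("list", n_permutations)
    got <- 0L
    while (got < n_permutations) {
      cand <- sort(sample.int(n, n1))
      key <- paste(cand, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        got <- got + 1L
        sets[[got]] <- cand
      }
    }
    exhaustive <- FALSE
  }
  B <- length(sets)
  # indicator matrix samples x permutations for vectorized class means
  Z <- matrix(0, n, B)
  for (b in seq_len(B)) Z[sets[[b]], b] <- 1
  Tot <- rowSums(values); Q <- rowSums(values^2)
  M1 <- (values %*% Z) / n1
  SQ1 <- (values^2 %*% Z)
  M2 <- (Tot - n1 * M1) / n2
  SS1 <- SQ1 - n1 * M1^2
  SS2 <- (Q - SQ1) - n2 * M2^2
  SS1[SS1 < 0] <- 0; SS2[SS2 < 0] <- 0
  S <- sqrt((1 / n1 + 1 / n2) * (SS1 + SS2) / (n - 2))
  Dperm <- abs((M1 - M2) / (S + s0))

  d_abs <- abs(obs$d)
  ord <- order(d_abs)                    # thresholds ascending
  thr <- d_abs[ord]
  p_feat <- length(thr)
  obs_count <- p_feat - seq_len(p_feat) + 1L   # #{|d| >= thr_j}
  tol <- 1e-10
  perm_counts <- matrix(0L, p_feat, B)
  for (b in seq_len(B)) {
    v <- sort(Dperm[, b])
    perm_counts[, b] <- p_feat - findInterval(thr - tol, v)
  }
  med_counts <- apply(perm_counts, 1L, stats::median)
  fdr <- pmin(1, med_counts / obs_count)
  # q_i = min FDR over thresholds t <= |d_i|: running minimum in ascending order
  q_at_thr <- cummin(fdr)
  q <- numeric(p_feat)
  q[ord] <- q_at_thr
  list(q = q, d = obs$d, s = obs$s, s0 = s0,
       n_permutations_used = B, exhaustive = exhaustive)
}

#' Full SAM analysis
#'
#' Convenience wrapper: estimates `s0`, computes the d-statistics and the
#' permutation q-values.
#'
#' @param values numeric feature x sample matrix.
#' @param labels two-class labels.
#' @param config a [pipeline_config] (uses `sam_n_permutations`,
#'   `sam_s0_percentiles`, `rng_seed`).
#' @param seed overrides `config$rng_seed` when given.
#' @return An object of class `sam_result`: list with per-feature `d`, `s`,
#'   `q`, `mean_diff`, plus `s0`, `classes`, `n_permutations_used`,
#'   `features`.
#' @export
sam_analysis <- function(values, labels, config = pipeline_config(),
                         seed = NULL) {
  values <- as.matrix(values)
  if (is.null(seed)) seed <- config$rng_seed
  s0 <- estimate_s0(values, labels, config$sam_s0_percentiles)
  stat <- sam_statistic(values, labels, s0 = s0)
  qres <- sam_qvalues(values, labels, s0 = s0,
                      n_permutations = config$sam_n_permutations, seed = seed)
  structure(list(d = stat$d, s = stat$s, q = qres$q,
                 mean_diff = stat$mean_diff, s0 = s0,
                 classes = stat$classes,
                 n_permutations_used = qres$n_permutations_used,
                 exhaustive = qres$exhaustive,
                 features = rownames(values)),
            class = "sam_result")
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("sam_result: %d features, classes %s vs %s, s0 = %.4g, %d permutations\n",
              length(x$d), x$classes[1L], x$classes[2L], x$s0,
              x$n_permutations_used))
  invisible(x)
}

#' Extract a subtype signature from a SAM result
#'
#' Features with q below the threshold, each tagged with the class in which
#' it is up-regulated (the sign of d). An empty signature is allowed.
#'
#' @param sam a `sam_result`.
#' @param q_threshold q cut-off (e.g. 0.02 for a 2% FDR).
#' @return A `data.frame` with columns `feature`, `d`, `q`, `up_in`.
#' @export
select_signature <- function(sam, q_threshold = 0.02) {
  stopifnot(inherits(sam, "sam_result"))
  keep <- which(sam$q < q_threshold)
  feats <- if (is.null(sam$features)) as.character(keep) else sam$features[keep]
  data.frame(feature = feats,
             d = sam$d[keep], q = sam$q[keep],
             up_in = ifelse(sam$d[keep] > 0, sam$classes[1L], sam$classes[2L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-class signature centroids
#'
#' Mean expression of each signature feature within each class of a training
#' matrix, for use by [classify_sample()].
#'
#' @param values numeric feature x sample training matrix.
#' @param labels two-class labels over its columns.
#' @param features signature feature IDs (rows of `values`).
#' @return A features x 2 numeric matrix with class names as columns.
#' @export
signature_centroids <- function(values, labels, features) {
  values <- as.matrix(values)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must define exactly two classes")
  features <- intersect(features, rownames(values))
  if (!length(features)) stop("no signature features present in the training matrix")
  vapply(levels(f), function(cl) {
    rowMeans(values[features, f == cl, drop = FALSE])
  }, numeric(length(features)))
}

#' Assign a new sample to a cluster by nearest signature centroid
#'
#' Spearman correlation between the profile and each class centroid over the
#' shared signature features; the class with the larger correlation wins.
#' The profile must cover at least half of the signature.
#'
#' @param profile named numeric expression vector for one sample.
#' @param centroids features x classes matrix from [signature_centroids()].
#' @return A list with `label` (class name) and `correlations` (named vector,
#'   one Spearman correlation per class).
#' @export
classify_sample <- function(profile, centroids) {
  shared <- intersect(names(profile), rownames(centroids))
  if (length(shared) < 0.5 * nrow(centroids)) {
    stop(sprintf("profile covers only %d of %d signature features (< 50%%)",
                 length(shared), nrow(centroids)))
  }
  cors <- apply(centroids[shared, , drop = FALSE], 2L, function(ctr) {
    stats::cor(profile[shared], ctr, method = "spearman")
  })
  list(label = names(cors)[which.max(cors)], correlations = cors)
}
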