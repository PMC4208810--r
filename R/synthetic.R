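#' Synthetic cohort specification
#'
#' Parameters of the generator that emulates the statistical structure the
#' pipeline assumes: two latent sample clusters; driver genes whose
#' copy-number state tracks the cluster and whose expression tracks the copy
#' dose; cluster-marker genes with a pure expression shift; null genes with
#' sporadic cluster-independent aberrations and independent expression;
#' gene sets enriched for markers of one cluster; log-normal IC50s with a
#' fold shift on differential drugs.
#'
#' Defaults describe a realistic desk-scale cohort: 60 samples split evenly,
#' 2000 genes of which 100 drivers and 200 markers, a dosage effect of 1
#' log2 unit per copy-dose unit, a 2 log2-unit marker shift (four times the
#' noise SD of 0.5), 50 gene sets of 15-25 genes with 10 differential, and
#' 20 drugs of which 5 carry an 8-fold IC50 shift (inside the 2-10 fold
#' range such panels show).
#'
#' @param n_samples number of samples.
#' @param n_genes total genes; markers are the remainder
#'   `n_genes - n_driver_genes - n_null_genes`.
#' @param n_driver_genes genes with cluster-correlated copy states and a
#'   dosage expression effect.
#' @param n_null_genes genes with background aberrations and independent
#'   expression.
#' @param cluster_proportions two probabilities summing to 1.
#' @param dose_effect log2 expression units per copy-dose unit (beta).
#' @param cluster_shift log2 shift applied to cluster-marker genes
#'   (half up in each cluster direction).
#' @param noise_sd residual SD in log2 units (sigma).
#' @param driver_purity probability that a driver gene carries its
#'   cluster-typical aberration in a sample of that cluster.
#' @param background_aberration_rate per-cell probability that a null gene
#'   is non-neutral (split evenly between GAIN and LOSS), independent of
#'   cluster and expression.
#' @param loh_rate per-cell probability of an LOH flag (independent layer).
#' @param n_gene_sets,n_differential_sets gene-set counts.
#' @param set_size length-2 range of member counts per set.
#' @param marker_fraction fraction of a differential set drawn from
#'   same-direction marker genes (rest from null genes).
#' @param n_drugs,n_differential_drugs drug counts.
#' @param ic50_fold fold IC50 shift of differential drugs between clusters.
#' @param ic50_cv log-scale spread (SD of natural-log IC50).
#' @param seed integer RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 60L, n_genes = 2000L,
                        n_driver_genes = 100L, n_null_genes = 1700L,
                        cluster_proportions = c(0.5, 0.5),
                        dose_effect = 1, cluster_shift = 2, noise_sd = 0.5,
                        driver_purity = 0.9,
                        background_aberration_rate = 0.3, loh_rate = 0.05,
                        n_gene_sets = 50L, n_differential_sets = 10L,
                        set_size = c(15L, 25L), marker_fraction = 0.8,
                        n_drugs = 20L, n_differential_drugs = 5L,
                        ic50_fold = 8, ic50_cv = 0.5, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_genes = as.integer(n_genes),
               n_driver_genes = as.integer(n_driver_genes),
               n_null_genes = as.integer(n_null_genes),
               cluster_proportions = cluster_proportions,
               dose_effect = dose_effect, cluster_shift = cluster_shift,
               noise_sd = noise_sd, driver_purity = driver_purity,
               background_aberration_rate = background_aberration_rate,
               loh_rate = loh_rate,
               n_gene_sets = as.integer(n_gene_sets),
               n_differential_sets = as.integer(n_differential_sets),
               set_size = as.integer(set_size),
               marker_fraction = marker_fraction,
               n_drugs = as.integer(n_drugs),
               n_differential_drugs = as.integer(n_differential_drugs),
               ic50_fold = ic50_fold, ic50_cv = ic50_cv,
               seed = as.integer(seed))
  spec$n_marker_genes <- spec$n_genes - spec$n_driver_genes - spec$n_null_genes
  stopifnot(spec$n_samples >= 4L, spec$n_genes > 0L,
            spec$n_driver_genes > 0L, spec$n_null_genes >= 0L,
            spec$n_marker_genes >= 0L,
            length(spec$cluster_proportions) == 2L,
            all(spec$cluster_proportions > 0),
            abs(sum(spec$cluster_proportions) - 1) < 1e-8,
            spec$noise_sd >= 0, spec$driver_purity > 0, spec$driver_purity <= 1,
            spec$background_aberration_rate >= 0,
            spec$background_aberration_rate < 1,
            spec$loh_rate >= 0, spec$loh_rate < 1,
            spec$n_differential_sets <= spec$n_gene_sets,
            length(spec$set_size) == 2L, spec$set_size[1L] <= spec$set_size[2L],
            spec$marker_fraction >= 0, spec$marker_fraction <= 1,
            spec$n_differential_drugs <= spec$n_drugs,
            spec$ic50_fold > 0, spec$ic50_cv > 0)
  if (spec$n_differential_sets > 0L && spec$n_marker_genes < 2L * spec$set_size[2L]) {
    stop("too few marker genes to populate differential gene sets")
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic paired copy-number / expression cohort
#'
#' Draws a cohort under the generative model described in [cohort_spec()]:
#' \itemize{
#'   \item Cluster sizes are fixed at `round(n_samples * proportions)` and
#'     sample-to-cluster assignment is a seeded permutation.
#'   \item Driver genes (half oriented each way) are GAIN in their high
#'     cluster and LOSS in the other with probability `driver_purity`, else
#'     NEUTRAL; expression is `baseline + dose_effect * dose + N(0, sd^2)`
#'     with dose coded LOSS = -1, NEUTRAL = 0, GAIN = +1.
#'   \item Marker genes are copy-neutral; half are shifted up in cluster 1
#'     and half up in cluster 2 by `cluster_shift / 2` each way.
#'   \item Null genes carry background aberrations independent of both
#'     cluster and expression.
#'   \item LOH flags form an independent random mask.
#'   \item Differential gene sets draw `marker_fraction` of their members
#'     from markers of a single direction (alternating by set), the rest
#'     from null genes; null sets draw uniformly.
#'   \item IC50s are log-normal with median 1 uM; differential drugs have
#'     their cluster-2 median multiplied by `ic50_fold` (cluster 1 is the
#'     sensitive cluster).
#' }
#'
#' @param spec a [cohort_spec].
#' @return A list with elements `calls` ([cn_calls]), `expr` (matrix),
#'   `gene_sets` ([gene_set_collection]), `ic50` ([ic50_table]), `truth`
#'   (list: `cluster` named vector, `drivers`, `marker_up1`, `marker_up2`,
#'   `differential_sets` data.frame, `differential_drugs`), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  n1 <- round(n * spec$cluster_proportions[1L])
  n1 <- max(2L, min(n - 2L, n1))
  cluster <- sample(rep(c(1L, 2L), c(n1, n - n1)))
  names(cluster) <- samples

  gid <- sprintf("G%05d", seq_len(spec$n_genes))
  drivers <- gid[seq_len(spec$n_driver_genes)]
  markers <- gid[spec$n_driver_genes + seq_len(spec$n_marker_genes)]
  nulls <- setdiff(gid, c(drivers, markers))
  half_d <- ceiling(length(drivers) / 2)
  driver_up1 <- drivers[seq_len(half_d)]          # GAIN in cluster 1
  half_m <- floor(length(markers) / 2)
  marker_up1 <- markers[seq_len(half_m)]
  marker_up2 <- setdiff(markers, marker_up1)

  state <- matrix("NEUTRAL", spec$n_genes, n, dimnames = list(gid, samples))
  baseline <- stats::rnorm(spec$n_genes, mean = 7, sd = 1)
  names(baseline) <- gid
  expr <- matrix(stats::rnorm(spec$n_genes * n, sd = spec$noise_sd),
                 spec$n_genes, n, dimnames = list(gid, samples)) + baseline

  for (g in drivers) {
    up_cluster <- if (g %in% driver_up1) 1L else 2L
    aberrant <- stats::runif(n) < spec$driver_purity
    st <- rep("NEUTRAL", n)
    st[aberrant & cluster == up_cluster] <- "GAIN"
    st[aberrant & cluster != up_cluster] <- "LOSS"
    state[g, ] <- st
    dose <- (st == "GAIN") - (st == "LOSS")
    expr[g, ] <- expr[g, ] + spec$dose_effect * dose
  }
  if (length(marker_up1)) {
    shift1 <- ifelse(cluster == 1L, spec$cluster_shift / 2, -spec$cluster_shift / 2)
    expr[marker_up1, ] <- expr[marker_up1, , drop = FALSE] +
      rep(shift1, each = length(marker_up1))
  }
  if (length(marker_up2)) {
    shift2 <- ifelse(cluster == 2L, spec$cluster_shift / 2, -spec$cluster_shift / 2)
    expr[marker_up2, ] <- expr[marker_up2, , drop = FALSE] +
      rep(shift2, each = length(marker_up2))
  }
  if (length(nulls) && spec$background_aberration_rate > 0) {
    u <- matrix(stats::runif(length(nulls) * n), length(nulls), n)
    st <- matrix("NEUTRAL", length(nulls), n)
    st[u < spec$background_aberration_rate / 2] <- "GAIN"
    st[u >= spec$background_aberration_rate / 2 &
         u < spec$background_aberration_rate] <- "LOSS"
    state[nulls, ] <- st
  }
  loh <- matrix(stats::runif(spec$n_genes * n) < spec$loh_rate,
                spec$n_genes, n, dimnames = list(gid, samples))
  calls <- cn_calls(state, loh)

  sets <- list()
  set_dirs <- integer(0)
  if (spec$n_gene_sets > 0L) {
    sizes <- sample(seq(spec$set_size[1L], spec$set_size[2L]),
                    spec$n_gene_sets, replace = TRUE)
    for (j in seq_len(spec$n_gene_sets)) {
      nm <- sprintf("PATHWAY_%03d", j)
      if (j <= spec$n_differential_sets) {
        dir_j <- if (j %% 2L == 1L) 1L else 2L
        pool <- if (dir_j == 1L) marker_up1 else marker_up2
        n_mark <- min(length(pool), round(spec$marker_fraction * sizes[j]))
        members <- c(sample(pool, n_mark),
                     sample(nulls, sizes[j] - n_mark))
        set_dirs <- c(set_dirs, dir_j)
      } else {
        members <- sample(gid, sizes[j])
      }
      sets[[nm]] <- members
    }
  }
  gene_sets <- gene_set_collection(sets)

  drugs <- sprintf("DRUG%02d", seq_len(spec$n_drugs))
  diff_drugs <- drugs[seq_len(spec$n_differential_drugs)]
  ic50_rows <- do.call(rbind, lapply(drugs, function(dg) {
    shift <- if (dg %in% diff_drugs) log(spec$ic50_fold) else 0
    log_ic50 <- ifelse(cluster == 2L, shift, 0) +
      stats::rnorm(n, sd = spec$ic50_cv)
    data.frame(drug = dg, sample = samples, ic50_uM = exp(log_ic50),
               censored = FALSE, stringsAsFactors = FALSE)
  }))
  ic50 <- ic50_table(ic50_rows$drug, ic50_rows$sample, ic50_rows$ic50_uM,
                     ic50_rows$censored)

  truth <- list(cluster = cluster,
                drivers = drivers,
                marker_up1 = marker_up1, marker_up2 = marker_up2,
                differential_sets = if (spec$n_differential_sets > 0L) {
                  data.frame(set = names(sets)[seq_len(spec$n_differential_sets)],
                             up_in_cluster = set_dirs, stringsAsFactors = FALSE)
                } else {
                  data.frame(set = character(0), up_in_cluster = integer(0))
                },
                differential_drugs = diff_drugs)
  list(calls = calls, expr = expr, gene_sets = gene_sets, ic50 = ic50,
       truth = truth, spec = spec)
}

#' Generate a structureless null cohort
#'
#' Same sampling machinery as [generate_cohort()] but with the dosage
#' effect, the marker shift and the drug fold all switched off, so no stage
#' of the pipeline should find signal. The truth lists are empty; the
#' (inconsequential) latent cluster assignment is kept so calibration tests
#' can form two groups.
#'
#' @param spec a [cohort_spec]; its effect-size fields are overridden.
#' @return Same structure as [generate_cohort()].
#' @export
generate_null_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  null_spec <- unclass(spec)
  null_spec$dose_effect <- 0
  null_spec$cluster_shift <- 0
  null_spec$ic50_fold <- 1
  null_spec$n_marker_genes <- NULL
  out <- generate_cohort(do.call(cohort_spec, null_spec))
  out$truth$drivers <- character(0)
  out$truth$marker_up1 <- character(0)
  out$truth$marker_up2 <- character(0)
  out$truth$differential_sets <- out$truth$differential_sets[0, , drop = FALSE]
  out$truth$differential_drugs <- character(0)
  out
}

#' Simulate a plain k-cluster expression matrix
#'
#' Minimal generator for clustering checks: `k` equally sized sample groups,
#' each with its own block of marker genes shifted by `shift` log2 units
#' against Gaussian noise. Used to probe cluster-number selection beyond the
#' two-cluster cohort generator.
#'
#' @param n_samples,n_genes matrix dimensions.
#' @param k number of planted clusters.
#' @param shift between-cluster marker shift (log2 units).
#' @param noise_sd residual SD.
#' @param markers_per_cluster marker genes per cluster.
#' @param seed RNG seed.
#' @return A list with `expr` (matrix) and `cluster` (named integer vector).
#' @export
simulate_expression_clusters <- function(n_samples = 30L, n_genes = 200L,
                                         k = 2L, shift = 2, noise_sd = 0.5,
                                         markers_per_cluster = 30L, seed = 1L) {
  stopifnot(k >= 1L, n_samples >= 2L * k,
            markers_per_cluster * k <= n_genes)
  set.seed(seed)
  samples <- sprintf("S%03d", seq_len(n_samples))
  gid <- sprintf("G%05d", seq_len(n_genes))
  sizes <- rep(n_samples %/% k, k)
  sizes[seq_len(n_samples %% k)] <- sizes[seq_len(n_samples %% k)] + 1L
  cluster <- sample(rep(seq_len(k), sizes))
  names(cluster) <- samples
  expr <- matrix(stats::rnorm(n_genes * n_samples, mean = 7, sd = noise_sd),
                 n_genes, n_samples, dimnames = list(gid, samples))
  for (j in seq_len(k)) {
    block <- gid[(j - 1L) * markers_per_cluster + seq_len(markers_per_cluster)]
    expr[block, cluster == j] <- expr[block, cluster == j] + shift
  }
  list(expr = expr, cluster = cluster)
}

#' Write a cohort's input files to a directory
#'
#' Writes the four standard inputs (`calls.tsv`, `expression.tsv`,
#' `gene_sets.gmt`, `ic50.tsv`) plus `truth.json`.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cn_calls(cohort$calls, file.path(dir, "calls.tsv"))
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_ic50(cohort$ic50, file.path(dir, "ic50.tsv"))
  truth <- cohort$truth
  truth$cluster <- as.list(truth$cluster)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
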