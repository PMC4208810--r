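`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a copy-number call object
#'
#' Gene-level copy-number calls for a panel of samples: a categorical state
#' (`LOSS`, `NEUTRAL`, `GAIN`) per gene and sample, plus an independent
#' loss-of-heterozygosity (LOH) flag. LOH may co-occur with any state
#' (copy-neutral LOH is common in aCGH calls), so gain/loss and LOH are kept
#' as separate layers.
#'
#' @param state character matrix (genes x samples) with entries in
#'   `"LOSS"`, `"NEUTRAL"`, `"GAIN"`; must carry unique row and column names.
#' @param loh logical matrix of the same dimensions flagging LOH; defaults to
#'   all `FALSE`.
#' @return An object of class `cn_calls`: a list with elements `genes`,
#'   `samples`, `state` and `loh`.
#' @export
cn_calls <- function(state, loh = NULL) {
  state <- as.matrix(state)
  if (is.null(loh)) {
    loh <- matrix(FALSE, nrow(state), ncol(state), dimnames = dimnames(state))
  }
  loh <- as.matrix(loh)
  if (!identical(dim(state), dim(loh))) {
    stop("'state' and 'loh' must have identical dimensions")
  }
  if (nrow(state) == 0L || ncol(state) == 0L) {
    dimnames(state) <- list(rownames(state) %||% character(0),
                            colnames(state) %||% character(0))
    dimnames(loh) <- dimnames(state)
  } else if (is.null(rownames(state)) || is.null(colnames(state))) {
    stop("'state' must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(state))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(state)[duplicated(rownames(state))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(state))) {
    stop("duplicate sample names: ",
         paste(unique(colnames(state)[duplicated(colnames(state))]), collapse = ", "))
  }
  bad <- matrix(!(state %in% c("LOSS", "NEUTRAL", "GAIN")),
                nrow(state), ncol(state))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid copy-number state '%s' at gene '%s', sample '%s'",
                 state[idx[1L], idx[2L]], rownames(state)[idx[1L]],
                 colnames(state)[idx[2L]]))
  }
  if (!is.logical(loh) || anyNA(loh)) stop("'loh' must be logical without NA")
  dimnames(loh) <- dimnames(state)
  structure(list(genes = rownames(state), samples = colnames(state),
                 state = state, loh = loh),
            class = "cn_calls")
}

#' @export
print.cn_calls <- function(x, ...) {
  cat(sprintf("cn_calls: %d genes x %d samples (%d GAIN, %d LOSS, %d LOH calls)\n",
              length(x$genes), length(x$samples),
              sum(x$state == "GAIN"), sum(x$state == "LOSS"), sum(x$loh)))
  invisible(x)
}

#' Validate an expression matrix
#'
#' Checks a numeric log2-scale expression matrix (genes x samples, one row per
#' gene, probe sets already collapsed): finite values and unique, non-empty
#' gene and sample identifiers. Returns the matrix unchanged so it can be used
#' inline.
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @return The validated numeric matrix.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values))) stop("duplicate sample names in expression matrix")
  if (!all(is.finite(values))) {
    idx <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]))
  }
  values
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors of member gene identifiers.
#'   Duplicate members within a set are dropped; empty sets are an error.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled empty string if missing).
#' @return An object of class `gene_set_collection`: the named list of member
#'   vectors with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) && is.null(names(sets))) stop("gene sets must be named")
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set: ", paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  if (length(descriptions) != length(sets)) stop("one description per set required")
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, member counts %s\n", length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Construct an IC50 table
#'
#' Long-format drug sensitivity records. `censored` flags IC50 values reported
#' at (or above) the top tested dose, i.e. right-censored non-responders.
#'
#' @param drug,sample character vectors.
#' @param ic50_uM positive numeric, micromolar.
#' @param censored logical.
#' @return A `data.frame` with class `ic50_table` prepended.
#' @export
ic50_table <- function(drug, sample, ic50_uM, censored = FALSE) {
  df <- data.frame(drug = as.character(drug), sample = as.character(sample),
                   ic50_uM = as.numeric(ic50_uM),
                   censored = as.logical(rep_len(censored, length(drug))),
                   stringsAsFactors = FALSE)
  if (anyNA(df)) stop("IC50 table must not contain missing values")
  if (any(df$ic50_uM <= 0)) {
    stop("non-positive IC50 for drug '",
         df$drug[df$ic50_uM <= 0][1L], "'")
  }
  key <- paste(df$drug, df$sample, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (drug, sample) pair: ",
         sub("\r", " / ", key[duplicated(key)][1L]))
  }
  class(df) <- c("ic50_table", "data.frame")
  df
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default. Defaults
#' follow common practice for this analysis: raw p < 0.05 jointly with
#' Spearman rho > 0.6 for driver selection; 500 resamples at 80% subsampling
#' for consensus clustering; 1000 label permutations and a 2% FDR signature
#' threshold for SAM; ssGSEA weighting exponent 0.25; pathway calls at
#' q < 0.2 with two-fold change.
#'
#' @param driver_p_threshold two-sided Mann-Whitney p cut-off for drivers.
#' @param driver_rho_threshold Spearman rho cut-off for drivers.
#' @param n_clusters number of integrative clusters (k).
#' @param consensus_n_resamples number of subsampling iterations.
#' @param consensus_subsample_fraction fraction of samples drawn per iteration.
#' @param sam_n_permutations label permutations for SAM q-values.
#' @param signature_q_threshold SAM q cut-off for the subtype signature.
#' @param pathway_q_threshold SAM q cut-off for subtype-specific pathways.
#' @param pathway_fc_up,pathway_fc_down fold-change bounds for UP/DOWN calls.
#' @param ssgsea_alpha rank weighting exponent of the enrichment score.
#' @param sam_s0_percentiles candidate quantiles of the scatter distribution
#'   searched for the SAM fudge factor s0.
#' @param rng_seed integer seed used by all stochastic stages.
#' @param min_group_size minimum samples per group for two-group tests.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(driver_p_threshold = 0.05,
                            driver_rho_threshold = 0.6,
                            n_clusters = 2L,
                            consensus_n_resamples = 500L,
                            consensus_subsample_fraction = 0.8,
                            sam_n_permutations = 1000L,
                            signature_q_threshold = 0.02,
                            pathway_q_threshold = 0.2,
                            pathway_fc_up = 2.0,
                            pathway_fc_down = 0.5,
                            ssgsea_alpha = 0.25,
                            sam_s0_percentiles = seq(0, 1, by = 0.05),
                            rng_seed = 1L,
                            min_group_size = 3L) {
  cfg <- list(driver_p_threshold = driver_p_threshold,
              driver_rho_threshold = driver_rho_threshold,
              n_clusters = as.integer(n_clusters),
              consensus_n_resamples = as.integer(consensus_n_resamples),
              consensus_subsample_fraction = consensus_subsample_fraction,
              sam_n_permutations = as.integer(sam_n_permutations),
              signature_q_threshold = signature_q_threshold,
              pathway_q_threshold = pathway_q_threshold,
              pathway_fc_up = pathway_fc_up,
              pathway_fc_down = pathway_fc_down,
              ssgsea_alpha = ssgsea_alpha,
              sam_s0_percentiles = sam_s0_percentiles,
              rng_seed = as.integer(rng_seed),
              min_group_size = as.integer(min_group_size))
  stopifnot(cfg$driver_p_threshold > 0, cfg$driver_p_threshold <= 1,
            cfg$driver_rho_threshold >= -1, cfg$driver_rho_threshold <= 1,
            cfg$n_clusters >= 2L,
            cfg$consensus_n_resamples >= 1L,
            cfg$consensus_subsample_fraction > 0,
            cfg$consensus_subsample_fraction <= 1,
            cfg$sam_n_permutations >= 1L,
            cfg$signature_q_threshold > 0,
            cfg$pathway_q_threshold > 0,
            cfg$pathway_fc_up > 0, cfg$pathway_fc_down > 0,
            cfg$ssgsea_alpha >= 0,
            all(cfg$sam_s0_percentiles >= 0), all(cfg$sam_s0_percentiles <= 1),
            cfg$min_group_size >= 1L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (length(val) > 4L) val <- c(val[1:3], "...")
    cat(sprintf("  %-30s %s\n", nm, paste(val, collapse = " ")))
  }
  invisible(x)
}
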