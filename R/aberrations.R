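#' Per-sample aberration burden
#'
#' Counts, for every sample, the genes called GAIN, the genes called LOSS and
#' the genes flagged LOH, optionally restricted to a gene subset (for example
#' a kinome list). The three flags are counted independently, so a gene with
#' LOSS and LOH contributes to both columns and the total is always the sum
#' of the three components.
#'
#' @param calls a [cn_calls] object.
#' @param gene_subset optional character vector of gene IDs; intersected with
#'   the genes present in `calls`.
#' @return A `data.frame` with columns `sample`, `gain_count`, `loss_count`,
#'   `loh_count`, `total_count`.
#' @export
count_aberrations <- function(calls, gene_subset = NULL) {
  stopifnot(inherits(calls, "cn_calls"))
  genes <- calls$genes
  if (!is.null(gene_subset)) {
    genes <- intersect(genes, gene_subset)
    if (!length(genes)) stop("gene_subset has no genes in common with the call matrix")
  }
  state <- calls$state[genes, , drop = FALSE]
  loh <- calls$loh[genes, , drop = FALSE]
  gain <- colSums(state == "GAIN")
  loss <- colSums(state == "LOSS")
  lohc <- colSums(loh)
  data.frame(sample = calls$samples,
             gain_count = as.integer(gain),
             loss_count = as.integer(loss),
             loh_count = as.integer(lohc),
             total_count = as.integer(gain + loss + lohc),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Recurrently aberrant genes
#'
#' Ranks genes by the number of samples carrying a given aberration type and
#' reports the recurrence frequency as a rounded integer percent. Ties are
#' broken lexicographically by gene ID so the output is deterministic.
#'
#' @param calls a [cn_calls] object.
#' @param aberration_type one of `"GAIN"`, `"LOSS"`, `"LOH"`.
#' @param top_n number of top-ranked genes to return (>= 1).
#' @return A `data.frame` with columns `gene`, `n_samples`, `frequency`
#'   (percent of samples, rounded to the nearest integer).
#' @export
recurrence_table <- function(calls, aberration_type = c("GAIN", "LOSS", "LOH"),
                             top_n = 15L) {
  stopifnot(inherits(calls, "cn_calls"), top_n >= 1L)
  aberration_type <- match.arg(aberration_type)
  n_total <- length(calls$samples)
  if (!length(calls$genes) || n_total == 0L) {
    return(data.frame(gene = character(0), n_samples = integer(0),
                      frequency = integer(0)))
  }
  n <- if (aberration_type == "LOH") {
    rowSums(calls$loh)
  } else {
    rowSums(calls$state == aberration_type)
  }
  ord <- order(-n, calls$genes)
  keep <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(gene = calls$genes[keep],
             n_samples = as.integer(n[keep]),
             frequency = as.integer(round_half_up(100 * n[keep] / n_total)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pathway-level aberration counts
#'
#' Aggregates gain/loss/LOH calls over the member genes of each pathway.
#' A pathway's count for a type is the number of (sample, member gene) cells
#' carrying that aberration; members absent from the call matrix contribute
#' zero. Both the per-sample breakdown and the across-sample aggregate are
#' returned, along with the top-ranked pathways per aberration type.
#'
#' @param calls a [cn_calls] object.
#' @param pathways a [gene_set_collection].
#' @param top_n how many top pathways to report per type (by aggregate count,
#'   ties broken by pathway name).
#' @return A list with elements `aggregate` (data.frame `pathway`, `gain`,
#'   `loss`, `loh`, `total`), `per_sample` (long data.frame `pathway`,
#'   `sample`, `gain`, `loss`, `loh`), and `top` (named list of the top
#'   `top_n` pathway names for `GAIN`, `LOSS`, `LOH`).
#' @export
pathway_aberration_counts <- function(calls, pathways, top_n = 10L) {
  stopifnot(inherits(calls, "cn_calls"), inherits(pathways, "gene_set_collection"))
  gain_m <- calls$state == "GAIN"
  loss_m <- calls$state == "LOSS"
  loh_m <- calls$loh
  per_sample <- do.call(rbind, lapply(names(pathways), function(p) {
    members <- intersect(pathways[[p]], calls$genes)
    if (length(members)) {
      data.frame(pathway = p, sample = calls$samples,
                 gain = as.integer(colSums(gain_m[members, , drop = FALSE])),
                 loss = as.integer(colSums(loss_m[members, , drop = FALSE])),
                 loh = as.integer(colSums(loh_m[members, , drop = FALSE])),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pathway = p, sample = calls$samples,
                 gain = 0L, loss = 0L, loh = 0L, stringsAsFactors = FALSE)
    }
  }))
  if (is.null(per_sample)) {
    per_sample <- data.frame(pathway = character(0), sample = character(0),
                             gain = integer(0), loss = integer(0), loh = integer(0))
  }
  agg <- do.call(rbind, lapply(split(per_sample, factor(per_sample$pathway,
                                                        levels = names(pathways))),
                               function(d) data.frame(pathway = d$pathway[1L],
                                                      gain = sum(d$gain),
                                                      loss = sum(d$loss),
                                                      loh = sum(d$loh))))
  if (is.null(agg)) {
    agg <- data.frame(pathway = character(0), gain = integer(0),
                      loss = integer(0), loh = integer(0))
  }
  rownames(agg) <- NULL
  agg$total <- agg$gain + agg$loss + agg$loh
  top <- lapply(c(GAIN = "gain", LOSS = "loss", LOH = "loh"), function(col) {
    ord <- order(-agg[[col]], agg$pathway)
    agg$pathway[ord[seq_len(min(top_n, nrow(agg)))]]
  })
  list(aggregate = agg, per_sample = per_sample, top = top)
}

# round-half-up to the nearest integer (13/18 -> 72, 10/18 -> 56)
round_half_up <- function(x) floor(x + 0.5)
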