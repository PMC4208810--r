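#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups. Ties receive half credit
#' through mid-ranks. The p-value is the exact permutation probability when
#' the combined sample size is at most 20 and there are no ties; otherwise
#' the normal approximation with tie and continuity correction is used.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return A list with `u_x` (U statistic of `x`), `u_min`
#'   (min of the two group statistics), `p_value` (two-sided, capped at 1)
#'   and `exact` (whether the exact distribution was used).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2 <= 20L) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value
  )
  list(u_x = u_x, u_min = min(u_x, n1 * n2 - u_x),
       p_value = min(p, 1), exact = exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; equals `1 - 6 * sum(d^2) / (n(n^2-1))`
#' when there are no ties. Constant input has no defined rank correlation and
#' is an error.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return The correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined rank correlation: constant input vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Select putative driver genes
#'
#' A driver gene is one whose copy-number aberration is concordant with its
#' own expression across samples. For each gene shared by the call and
#' expression matrices (matched by identifier and sample name):
#' \enumerate{
#'   \item the gene's direction is the more frequent of GAIN/LOSS among its
#'     non-neutral states (ties go to GAIN);
#'   \item a two-sided Mann-Whitney test compares expression in samples with
#'     the directional state against samples with the NEUTRAL state;
#'   \item Spearman rho is computed between the numeric copy dose
#'     (LOSS = -1, NEUTRAL = 0, GAIN = +1; LOH carries no dosage and is
#'     ignored) and expression over all shared samples.
#' }
#' A gene is selected when `p < driver_p_threshold` and
#' `rho > driver_rho_threshold`; because dose and expression are oriented the
#' same way, concordant LOSS-driven genes also yield positive rho. Genes that
#' cannot be tested (no aberrant samples, groups below `min_group_size`,
#' constant dose or expression) are reported with `selected = FALSE` and a
#' reason code.
#'
#' @param calls a [cn_calls] object.
#' @param expr numeric expression matrix (genes x samples).
#' @param config a [pipeline_config].
#' @return A `data.frame` with one row per shared gene: `gene`, `direction`,
#'   `n_aberrant`, `n_neutral`, `u_statistic`, `p_value`, `rho`, `selected`,
#'   `reason` (`"ok"` when testable). The numbers of genes dropped from each
#'   matrix are attached as attributes `n_dropped_calls` / `n_dropped_expr`.
#' @export
select_drivers <- function(calls, expr, config = pipeline_config()) {
  stopifnot(inherits(calls, "cn_calls"))
  expr <- expression_matrix(expr)
  shared_samples <- intersect(calls$samples, colnames(expr))
  if (!length(shared_samples)) stop("no samples shared between call and expression matrices")
  shared_genes <- sort(intersect(calls$genes, rownames(expr)))
  if (!length(shared_genes)) stop("no genes shared between call and expression matrices")
  n_dropped_calls <- length(calls$genes) - length(shared_genes)
  n_dropped_expr <- nrow(expr) - length(shared_genes)
  if (n_dropped_calls || n_dropped_expr) {
    message(sprintf("select_drivers: dropped %d call-only and %d expression-only genes",
                    n_dropped_calls, n_dropped_expr))
  }
  state <- calls$state[shared_genes, shared_samples, drop = FALSE]
  e <- expr[shared_genes, shared_samples, drop = FALSE]
  min_n <- config$min_group_size
  rows <- lapply(seq_along(shared_genes), function(i) {
    s <- state[i, ]
    x <- e[i, ]
    n_gain <- sum(s == "GAIN"); n_loss <- sum(s == "LOSS")
    direction <- if (n_loss > n_gain) "LOSS" else "GAIN"
    rec <- list(gene = shared_genes[i], direction = direction,
                n_aberrant = if (direction == "GAIN") n_gain else n_loss,
                n_neutral = sum(s == "NEUTRAL"),
                u_statistic = NA_real_, p_value = NA_real_, rho = NA_real_,
                selected = FALSE, reason = "ok")
    if (n_gain + n_loss == 0L) {
      rec$reason <- "no_aberrant_samples"
      return(rec)
    }
    if (rec$n_aberrant < min_n || rec$n_neutral < min_n) {
      rec$reason <- "group_below_min_size"
      return(rec)
    }
    dose <- (s == "GAIN") - (s == "LOSS")
    if (stats::sd(x) == 0 || stats::sd(dose) == 0) {
      rec$reason <- "constant_input"
      return(rec)
    }
    mw <- mann_whitney_u(x[s == direction], x[s == "NEUTRAL"])
    rec$u_statistic <- mw$u_min
    rec$p_value <- mw$p_value
    rec$rho <- spearman_rho(dose, x)
    rec$selected <- (rec$p_value < config$driver_p_threshold) &&
      (rec$rho > config$driver_rho_threshold)
    rec
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "n_dropped_calls") <- n_dropped_calls
  attr(out, "n_dropped_expr") <- n_dropped_expr
  out
}

#' Write a driver-gene report
#'
#' @param drivers output of [select_drivers()].
#' @param path output TSV path.
#' @export
write_driver_report <- function(drivers, path) {
  utils::write.table(drivers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
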