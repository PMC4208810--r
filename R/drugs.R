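#' Serial dilution concentration series
#'
#' Final assay concentrations for a serial dilution: stock concentrations
#' `start / ratio^i` for `i = 0 .. n_points - 1`, each multiplied by the
#' assay dilution factor (0.5 when compound is added to cells in an equal
#' volume).
#'
#' @param start_uM starting stock concentration in micromolar (> 0).
#' @param ratio dilution ratio between consecutive points (> 1).
#' @param n_points number of concentrations (>= 1).
#' @param assay_dilution factor applied on addition to the assay plate.
#' @return Numeric vector of final concentrations in micromolar, descending.
#' @export
dilution_series <- function(start_uM = 200, ratio = 4, n_points = 9L,
                            assay_dilution = 0.5) {
  if (start_uM <= 0) stop("start_uM must be positive")
  if (ratio <= 1) stop("ratio must exceed 1")
  if (n_points < 1L) stop("n_points must be at least 1")
  if (assay_dilution <= 0) stop("assay_dilution must be positive")
  start_uM * ratio^(-(seq_len(n_points) - 1)) * assay_dilution
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`
#' on log-concentration, with multi-start initialization over a grid of
#' IC50 and Hill-slope starting values (Levenberg-Marquardt via
#' \pkg{minpack.lm}). When the fitted IC50 exceeds the highest tested
#' concentration the value is right-censored and reported at that top
#' concentration.
#'
#' @param concentrations positive concentrations in micromolar (>= 4 points).
#' @param viabilities matching normalized viability fractions.
#' @return A list with `ic50_uM`, `hill`, `top`, `bottom`, `converged`,
#'   `censored`. When no start converges, `converged` is `FALSE` and the
#'   parameters are `NA`.
#' @export
fit_ic50 <- function(concentrations, viabilities) {
  if (length(concentrations) != length(viabilities)) {
    stop("concentrations and viabilities must have equal length")
  }
  if (length(concentrations) < 4L) stop("need at least 4 concentration points")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  x <- log10(concentrations)
  v <- as.numeric(viabilities)
  df <- data.frame(x = x, v = v)
  l_starts <- unique(as.numeric(stats::quantile(x, c(0.25, 0.5, 0.75))))
  hill_starts <- c(0.5, 1, 2, 4)
  best <- NULL
  for (l0 in l_starts) {
    for (h0 in hill_starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          v ~ bottom + (top - bottom) / (1 + 10^(hill * (x - l50))),
          data = df,
          start = list(bottom = min(v), top = max(v), hill = h0, l50 = l0),
          lower = c(bottom = -0.5, top = 0, hill = 0.01,
                    l50 = min(x) - 6),
          upper = c(bottom = 1.5, top = 2.5, hill = 20,
                    l50 = max(x) + 6),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(list(ic50_uM = NA_real_, hill = NA_real_, top = NA_real_,
                bottom = NA_real_, converged = FALSE, censored = NA))
  }
  p <- as.list(stats::coef(best$fit))
  ic50 <- 10^p$l50
  # right-censor when half inhibition is not reached in the tested range:
  # fitted IC50 beyond the top dose, or the fitted curve stays above 0.5
  # viability (normalized fraction) at the top tested concentration, as for
  # a flat non-responder
  pred_top_dose <- p$bottom + (p$top - p$bottom) /
    (1 + 10^(p$hill * (max(x) - p$l50)))
  censored <- ic50 > max(concentrations) || pred_top_dose > 0.5
  if (censored) ic50 <- max(concentrations)
  list(ic50_uM = ic50, hill = p$hill, top = p$top, bottom = p$bottom,
       converged = TRUE, censored = censored)
}

#' Compare IC50 between two clusters for one drug
#'
#' Two-sided Mann-Whitney test on log10 IC50 between the samples of the two
#' clusters (rank-based, so the p-value is identical on the raw scale), with
#' medians per cluster and their fold difference. Censored IC50 values are
#' included at their capped value; tied ranks get half credit.
#'
#' @param ic50 an [ic50_table].
#' @param labels named vector mapping sample to cluster (exactly two
#'   clusters among the drug's samples).
#' @param drug drug name to test.
#' @param min_group_size minimum samples with an IC50 per cluster.
#' @return A one-row `data.frame`: `drug`, `cluster1`, `cluster2`,
#'   `median1_uM`, `median2_uM`, `fold_difference` (larger median over
#'   smaller), `u_statistic`, `p_value`, `n1`, `n2`, `sensitive_cluster`.
#' @export
compare_clusters <- function(ic50, labels, drug, min_group_size = 3L) {
  rows <- ic50[ic50$drug == drug, , drop = FALSE]
  rows <- rows[rows$sample %in% names(labels), , drop = FALSE]
  if (!nrow(rows)) stop("no IC50 records for drug '", drug, "' with cluster labels")
  cl <- labels[rows$sample]
  clusters <- sort(unique(as.character(cl)))
  if (length(clusters) != 2L) {
    stop("expected exactly 2 clusters among samples for drug '", drug,
         "', found ", length(clusters))
  }
  v1 <- rows$ic50_uM[cl == clusters[1L]]
  v2 <- rows$ic50_uM[cl == clusters[2L]]
  if (length(v1) < min_group_size || length(v2) < min_group_size) {
    stop(sprintf("drug '%s': fewer than %d samples per cluster (%d vs %d)",
                 drug, min_group_size, length(v1), length(v2)))
  }
  mw <- mann_whitney_u(log10(v1), log10(v2))
  med1 <- stats::median(v1); med2 <- stats::median(v2)
  data.frame(drug = drug, cluster1 = clusters[1L], cluster2 = clusters[2L],
             median1_uM = med1, median2_uM = med2,
             fold_difference = max(med1, med2) / min(med1, med2),
             u_statistic = mw$u_min, p_value = mw$p_value,
             n1 = length(v1), n2 = length(v2),
             sensitive_cluster = if (med1 <= med2) clusters[1L] else clusters[2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare IC50 between clusters for every drug
#'
#' Applies [compare_clusters()] to each drug present in the table; drugs
#' with too few labelled samples per cluster are reported with `NA`
#' statistics and a reason.
#'
#' @param ic50 an [ic50_table].
#' @param labels named sample -> cluster vector.
#' @param min_group_size minimum samples per cluster.
#' @return A `data.frame`, one row per drug, ordered by ascending p-value;
#'   untestable drugs last with `reason` filled in.
#' @export
compare_all_drugs <- function(ic50, labels, min_group_size = 3L) {
  drugs <- unique(ic50$drug)
  rows <- lapply(drugs, function(dg) {
    res <- tryCatch(compare_clusters(ic50, labels, dg, min_group_size),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      data.frame(drug = dg, cluster1 = NA_character_, cluster2 = NA_character_,
                 median1_uM = NA_real_, median2_uM = NA_real_,
                 fold_difference = NA_real_, u_statistic = NA_real_,
                 p_value = NA_real_, n1 = NA_integer_, n2 = NA_integer_,
                 sensitive_cluster = NA_character_, reason = res,
                 stringsAsFactors = FALSE)
    } else {
      res$reason <- ""
      res
    }
  })
  out <- do.call(rbind, rows)
  out[order(is.na(out$p_value), out$p_value, out$drug), , drop = FALSE]
}
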