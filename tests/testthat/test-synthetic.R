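small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_samples = 24L, n_genes = 120L, n_driver_genes = 20L,
              n_null_genes = 80L, n_gene_sets = 8L, n_differential_sets = 4L,
              set_size = c(5L, 8L), n_drugs = 6L, n_differential_drugs = 2L,
              seed = seed, ...)
}

test_that("generation is bit-identical under the same seed", {
  a <- generate_cohort(small_spec(seed = 5))
  b <- generate_cohort(small_spec(seed = 5))
  expect_identical(a$calls$state, b$calls$state)
  expect_identical(a$expr, b$expr)
  expect_identical(unclass(a$gene_sets), unclass(b$gene_sets))
  expect_identical(a$ic50$ic50_uM, b$ic50$ic50_uM)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(small_spec(seed = 6))
  expect_false(identical(a$expr, c$expr))
})

test_that("the noise-free limit gives perfect dose concordance for drivers", {
  co <- generate_cohort(small_spec(seed = 7, noise_sd = 0))
  for (g in co$truth$drivers[1:5]) {
    s <- co$calls$state[g, ]
    dose <- (s == "GAIN") - (s == "LOSS")
    if (length(unique(dose)) >= 2) {
      expect_equal(spearman_rho(dose, co$expr[g, ]), 1)
    }
  }
})

test_that("generated objects satisfy their invariants and round-trip", {
  co <- generate_cohort(small_spec(seed = 8))
  expect_s3_class(co$calls, "cn_calls")
  expect_true(all(is.finite(co$expr)))
  expect_true(all(lengths(co$gene_sets) > 0))
  expect_true(all(co$ic50$ic50_uM > 0))
  expect_setequal(unique(co$truth$cluster), 1:2)
  expect_identical(names(co$truth$cluster), colnames(co$expr))

  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_identical(read_cn_calls(file.path(dir, "calls.tsv"))$state,
                   co$calls$state)
  expect_identical(read_expression(file.path(dir, "expression.tsv")), co$expr)
  expect_identical(unclass(read_gmt(file.path(dir, "gene_sets.gmt")))[seq_along(co$gene_sets)],
                   unclass(co$gene_sets)[seq_along(co$gene_sets)])
  expect_equal(read_ic50(file.path(dir, "ic50.tsv"))$ic50_uM, co$ic50$ic50_uM)
})

test_that("differential gene sets draw from markers of the stated cluster", {
  co <- generate_cohort(small_spec(seed = 9))
  truth <- co$truth$differential_sets
  for (i in seq_len(nrow(truth))) {
    members <- co$gene_sets[[truth$set[i]]]
    pool <- if (truth$up_in_cluster[i] == 1) co$truth$marker_up1 else co$truth$marker_up2
    expect_gte(mean(members %in% pool), 0.5)
  }
})

test_that("the null cohort carries no planted structure", {
  co <- generate_null_cohort(small_spec(seed = 10))
  expect_length(co$truth$drivers, 0)
  expect_length(co$truth$differential_drugs, 0)
  expect_identical(nrow(co$truth$differential_sets), 0L)

  # drug IC50s share one distribution: fold shift absent by construction
  labels <- stats::setNames(paste0("C", co$truth$cluster), names(co$truth$cluster))
  cmp <- compare_all_drugs(co$ic50, labels)
  expect_true(all(cmp$fold_difference < 4, na.rm = TRUE))
})

test_that("driver selection on null cohorts is calibrated at the p threshold", {
  rates <- vapply(1:5, function(seed) {
    co <- generate_null_cohort(cohort_spec(n_samples = 40L, n_genes = 400L,
                                           n_driver_genes = 40L,
                                           n_null_genes = 320L,
                                           n_gene_sets = 5L,
                                           n_differential_sets = 0L,
                                           set_size = c(5L, 8L),
                                           seed = seed))
    dr <- select_drivers(co$calls, co$expr)
    testable <- dr$reason == "ok"
    sum(dr$selected[testable]) / max(sum(testable), 1)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)  # conjunction with rho makes this conservative
})

test_that("consensus on a null cohort at k = 2 lacks a stable split", {
  co <- generate_null_cohort(small_spec(seed = 12))
  cfg <- pipeline_config(consensus_n_resamples = 100L)
  res <- consensus_cluster(co$expr, rownames(co$expr)[1:60], k_range = 2,
                           config = cfg, seed = 12)
  cm <- res$consensus[["2"]]
  # the latent generative labels carry no signal, so no consensus gap exists
  lab <- co$truth$cluster[rownames(cm)]
  same <- outer(lab, lab, `==`)
  off <- upper.tri(cm)
  gap <- mean(cm[off & same]) - mean(cm[off & !same])
  expect_lt(gap, 0.3)
  # and the inferred split is far less crisp than on separated data
  v <- cm[off]
  expect_gt(mean(v > 0.05 & v < 0.95), 0.2)
})

test_that("pathway calls on null cohorts are silent", {
  calls_per_seed <- vapply(1:3, function(seed) {
    co <- generate_null_cohort(small_spec(seed = seed + 20))
    es <- rank_normalize(ssgsea_matrix(co$expr, co$gene_sets))
    labels <- stats::setNames(paste0("C", co$truth$cluster),
                              names(co$truth$cluster))
    cfg <- pipeline_config(sam_n_permutations = 300L)
    pw <- subtype_pathways(es, labels[colnames(es)], cfg)
    sum(pw$call != "NONE")
  }, numeric(1))
  expect_lte(stats::median(calls_per_seed), 0)
})
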