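test_that("Spearman distance has the expected geometry", {
  set.seed(5)
  base <- rnorm(10)
  expr <- cbind(a = base, b = base, c = -base)  # duplicate and rank-reversal
  rownames(expr) <- paste0("g", 1:10)
  d <- spearman_distance_matrix(expr)
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 2)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  # closed-form check on three hand-made profiles
  expr3 <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(4, 3, 2, 1))
  rownames(expr3) <- paste0("g", 1:4)
  d3 <- spearman_distance_matrix(expr3)
  expect_equal(unname(d3["x", "y"]), 1 - (1 - 6 * 2 / (4 * 15)))
  expect_equal(unname(d3["x", "z"]), 2)

  const <- cbind(a = rep(1, 5), b = rnorm(5))
  rownames(const) <- paste0("g", 1:5)
  expect_error(spearman_distance_matrix(const), "constant expression profile.*a")
})

test_that("average linkage reproduces a hand-computed UPGMA tree", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["a", "c"] <- d["c", "a"] <- 4
  d["a", "d"] <- d["d", "a"] <- 5
  d["b", "c"] <- d["c", "b"] <- 4.5
  d["b", "d"] <- d["d", "b"] <- 5.5
  d["c", "d"] <- d["d", "c"] <- 2
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # merges: {a,b} at 1, {c,d} at 2, then mean of the 4 cross distances
  expect_equal(hc$height, c(1, 2, (4 + 5 + 4.5 + 5.5) / 4))
  lab <- average_linkage_cluster(d, 2)
  expect_equal(unname(lab), c(1, 1, 2, 2))
  expect_identical(unname(average_linkage_cluster(d, 4)), 1:4)  # k = n
  expect_error(average_linkage_cluster(d, 5), "exceeds")
})

test_that("identical points cluster together at any k = 2 cut", {
  expr <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                c = c(4, 3, 2, 1), d = c(4, 3, 2, 1))
  rownames(expr) <- paste0("g", 1:4)
  lab <- average_linkage_cluster(spearman_distance_matrix(expr), 2)
  expect_equal(lab[["a"]], lab[["b"]])
  expect_equal(lab[["c"]], lab[["d"]])
  expect_true(lab[["a"]] != lab[["c"]])
})

test_that("consensus matrices are symmetric, unit-diagonal and in [0,1]", {
  sim <- simulate_expression_clusters(n_samples = 16, n_genes = 40, k = 2,
                                      markers_per_cluster = 15, seed = 2)
  cfg <- pipeline_config(consensus_n_resamples = 50L)
  res <- consensus_cluster(sim$expr, rownames(sim$expr), k_range = 2:3,
                           config = cfg, seed = 2)
  for (cm in res$consensus) {
    expect_equal(cm, t(cm))
    expect_true(all(cm >= 0 & cm <= 1))
    expect_true(all(diag(cm)[diag(res$cosample_counts) > 0] == 1))
  }
  expect_true(all(vapply(res$labels, function(l) length(unique(l)), 1L) ==
                    res$k_range))
})

test_that("no resampling variability gives a binary consensus matrix", {
  sim <- simulate_expression_clusters(n_samples = 12, n_genes = 40, k = 2,
                                      markers_per_cluster = 15, seed = 4)
  cfg <- pipeline_config(consensus_n_resamples = 25L,
                         consensus_subsample_fraction = 1.0)
  res <- consensus_cluster(sim$expr, rownames(sim$expr), k_range = 2,
                           config = cfg, seed = 4)
  expect_true(all(res$consensus[["2"]] %in% c(0, 1)))
})

test_that("consensus clustering is deterministic given the seed", {
  sim <- simulate_expression_clusters(n_samples = 14, n_genes = 40, k = 2,
                                      markers_per_cluster = 15, seed = 6)
  cfg <- pipeline_config(consensus_n_resamples = 40L)
  a <- consensus_cluster(sim$expr, rownames(sim$expr), k_range = 2:3,
                         config = cfg, seed = 9)
  b <- consensus_cluster(sim$expr, rownames(sim$expr), k_range = 2:3,
                         config = cfg, seed = 9)
  expect_identical(a$consensus, b$consensus)
  expect_identical(a$labels, b$labels)
})

test_that("well-separated clusters give near-binary consensus and ARI 1", {
  sim <- simulate_expression_clusters(n_samples = 24, n_genes = 60, k = 2,
                                      shift = 2, noise_sd = 0.5,
                                      markers_per_cluster = 30, seed = 8)
  cfg <- pipeline_config(consensus_n_resamples = 100L)
  res <- consensus_cluster(sim$expr, rownames(sim$expr), k_range = 2,
                           config = cfg, seed = 8)
  cm <- res$consensus[["2"]]
  same <- outer(sim$cluster, sim$cluster, `==`)
  off <- upper.tri(cm)
  expect_gte(min(cm[off & same]), 0.95)
  expect_lte(max(cm[off & !same]), 0.05)
  expect_equal(ari(res$labels[["2"]], sim$cluster), 1)
})

test_that("a single planted cluster leaves the k = 2 consensus unstable", {
  set.seed(10)
  expr <- matrix(rnorm(60 * 24, mean = 7, sd = 0.5), 60, 24,
                 dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:24)))
  cfg <- pipeline_config(consensus_n_resamples = 100L)
  res <- consensus_cluster(expr, rownames(expr), k_range = 2, config = cfg,
                           seed = 10)
  v <- res$consensus[["2"]][upper.tri(res$consensus[["2"]])]
  expect_gte(mean(v > 0.2 & v < 0.8), 0.25)  # substantial ambiguous mass
})

test_that("select_k prefers the smallest k on flat statistics", {
  flat <- data.frame(k = 2:5, auc = rep(0.4, 4))
  expect_identical(select_k(flat)$k, 2L)
})
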