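test_that("Mann-Whitney matches hand-enumerated reference cases", {
  r1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$u_min, 0)
  expect_equal(r1$p_value, 0.1)          # 2 * 1/20 over C(6,3) assignments

  r2 <- mann_whitney_u(c(1, 4), c(2, 3)) # symmetric ranks
  expect_equal(r2$p_value, 1)

  r3 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r3$u_min, 1)
  expect_equal(r3$p_value, 2 / 3)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney exact p equals enumeration for random tie-free groups", {
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    v <- sample(seq_len(50), n1 + n2)    # distinct -> tie-free
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y)$p_value, mw_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("ties switch to the corrected normal approximation", {
  r <- mann_whitney_u(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_false(r$exact)
  expect_lte(r$p_value, 1)
  # half credit for the tied observations via mid-ranks
  expect_equal(r$u_x, sum(rank(c(1, 2, 2, 3, 2, 4, 5, 6))[1:4]) - 10)
})

test_that("Spearman rho covers monotone, antitone and tied closed forms", {
  expect_equal(spearman_rho(1:4, c(10, 20, 30, 40)), 1)
  expect_equal(spearman_rho(1:4, c(40, 30, 20, 10)), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2)), 0.5)  # 1 - 6*2/24
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

make_driver_fixture <- function(states, expr_values, gene = "g1") {
  samples <- sprintf("s%02d", seq_along(states))
  st <- matrix(states, nrow = 1, dimnames = list(gene, samples))
  e <- matrix(expr_values, nrow = 1, dimnames = list(gene, samples))
  list(calls = cn_calls(st), expr = e)
}

test_that("perfectly dose-concordant genes are selected", {
  fx <- make_driver_fixture(rep(c("GAIN", "NEUTRAL"), each = 5),
                            c(1, 1.1, 1.2, 1.3, 1.4, 0, 0.1, 0.2, 0.3, 0.4))
  res <- select_drivers(fx$calls, fx$expr)
  expect_true(res$selected)
  expect_identical(res$direction, "GAIN")
  expect_gt(res$rho, 0.6)
  expect_lt(res$p_value, 0.05)
})

test_that("concordant LOSS-driven genes yield positive rho and are selected", {
  fx <- make_driver_fixture(rep(c("LOSS", "NEUTRAL"), each = 5),
                            c(0, 0.1, 0.2, 0.3, 0.4, 1, 1.1, 1.2, 1.3, 1.4))
  res <- select_drivers(fx$calls, fx$expr)
  expect_identical(res$direction, "LOSS")
  expect_gt(res$rho, 0.6)   # lower dose with lower expression is concordant
  expect_true(res$selected)
})

test_that("selection needs both the p and the rho threshold", {
  # 3v3: smallest possible exact p is 0.1 > 0.05, so rho alone cannot select
  fx <- make_driver_fixture(rep(c("GAIN", "NEUTRAL"), each = 3),
                            c(3, 4, 5, 0, 1, 2))
  res <- select_drivers(fx$calls, fx$expr)
  expect_gt(res$rho, 0.6)
  expect_gte(res$p_value, 0.05)
  expect_false(res$selected)
})

test_that("untestable genes carry reason codes instead of statistics", {
  fx <- make_driver_fixture(rep("NEUTRAL", 6), rnorm(6))
  res <- select_drivers(fx$calls, fx$expr)
  expect_false(res$selected)
  expect_identical(res$reason, "no_aberrant_samples")

  fx2 <- make_driver_fixture(c("GAIN", "GAIN", rep("NEUTRAL", 4)), rnorm(6))
  res2 <- select_drivers(fx2$calls, fx2$expr)
  expect_identical(res2$reason, "group_below_min_size")
})

test_that("driver selection is invariant to sample and gene ordering", {
  co <- generate_cohort(cohort_spec(n_samples = 20L, n_genes = 60L,
                                    n_driver_genes = 10L, n_null_genes = 40L,
                                    n_gene_sets = 5L, n_differential_sets = 2L,
                                    set_size = c(3L, 5L), seed = 3L))
  base <- select_drivers(co$calls, co$expr)
  perm_s <- sample(co$calls$samples)
  perm_g <- sample(co$calls$genes)
  shuffled <- cn_calls(co$calls$state[perm_g, perm_s],
                       co$calls$loh[perm_g, perm_s])
  res <- select_drivers(shuffled, co$expr[rev(rownames(co$expr)), ])
  expect_setequal(res$gene[res$selected], base$gene[base$selected])
})
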