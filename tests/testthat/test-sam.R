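two_class <- function(n1, n2) rep(c("A", "B"), c(n1, n2))

test_that("the d-statistic matches its closed form", {
  x <- rbind(f1 = c(1, 2, 3, 4, 5, 6))
  st <- sam_statistic(x, two_class(3, 3), s0 = 0)
  expect_equal(unname(st$d), -3 / sqrt(2 / 3))   # hand computation
  expect_equal(unname(st$s), sqrt((2 / 3) * (2 + 2) / 4))

  eq <- rbind(f1 = c(1, 2, 3, 1, 2, 3))
  expect_equal(unname(sam_statistic(eq, two_class(3, 3), 0)$d), 0)

  # s0 -> infinity shrinks every d toward 0
  big <- sam_statistic(x, two_class(3, 3), s0 = 1e9)
  expect_lt(abs(big$d), 1e-8)
  expect_error(sam_statistic(x, rep(c("A", "B"), c(5, 1))), "at least 2")
})

test_that("s0 estimation returns 0 for homoscedastic features and stabilizes |d|", {
  set.seed(21)
  labels <- two_class(5, 5)
  # identical scatter across features -> 0
  x_ident <- matrix(rep(rnorm(10), each = 30), 30, 10)
  expect_equal(estimate_s0(x_ident, labels), 0)

  # scatter spanning two orders of magnitude: chosen s0 > 0 and the spread
  # of |d| across scatter windows shrinks against s0 = 0
  scales <- 10^runif(300, -1, 1)
  x <- matrix(rnorm(300 * 10), 300, 10) * scales
  s0 <- estimate_s0(x, labels)
  expect_gt(s0, 0)
  cv_at <- function(s0c) {
    st <- sam_statistic(x, labels, 0)
    d <- st$mean_diff / (st$s + s0c)
    w <- cut(st$s, stats::quantile(st$s, 0:10 / 10), include.lowest = TRUE)
    m <- tapply(abs(d), w, stats::median)
    stats::sd(m) / mean(m)
  }
  expect_lt(cv_at(s0), cv_at(0))

  # a single candidate percentile is returned as-is
  st <- sam_statistic(x, labels, 0)
  expect_equal(estimate_s0(x, labels, percentiles = 0.5),
               unname(stats::quantile(st$s, 0.5)))
})

test_that("exhaustive permutations make q-values seed-independent", {
  set.seed(31)
  x <- matrix(rnorm(40), 10, 4)
  labels <- two_class(2, 2)               # C(4,2) = 6 distinct assignments
  q1 <- sam_qvalues(x, labels, s0 = 0.1, n_permutations = 100, seed = 1)
  q2 <- sam_qvalues(x, labels, s0 = 0.1, n_permutations = 100, seed = 99)
  expect_true(q1$exhaustive)
  expect_identical(q1$q, q2$q)
})

test_that("q-values live in [0,1], are monotone in |d| and label-swap invariant", {
  set.seed(32)
  x <- matrix(rnorm(50 * 12), 50, 12)
  x[1:5, 1:6] <- x[1:5, 1:6] + 3
  labels <- two_class(6, 6)
  r <- sam_qvalues(x, labels, s0 = 0.05, n_permutations = 200, seed = 5)
  expect_true(all(r$q >= 0 & r$q <= 1))
  ord <- order(abs(r$d), decreasing = TRUE)
  expect_true(all(diff(r$q[ord]) >= 0))   # non-decreasing as |d| falls

  swapped <- sam_qvalues(x, rev(labels), s0 = 0.05, n_permutations = 200, seed = 5)
  # swapping the class labels flips d but leaves |d| and q unchanged
  expect_equal(swapped$d, -r$d)
  expect_equal(swapped$q, r$q)
})

test_that("signature extraction respects the q threshold and direction", {
  set.seed(33)
  x <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%d", 1:8)))
  x[1:3, 1:4] <- x[1:3, 1:4] + 4
  sam <- sam_analysis(x, two_class(4, 4),
                      config = pipeline_config(sam_n_permutations = 200L))
  sig <- select_signature(sam, q_threshold = 0.05)
  expect_true(all(sig$feature %in% sprintf("f%02d", 1:3)))
  expect_true(all(sig$up_in == "A"))

  none <- sam
  none$q[] <- 1
  expect_identical(nrow(select_signature(none, 0.5)), 0L)
  all_sig <- select_signature(sam, q_threshold = 1.0 + 1e-9)
  expect_identical(nrow(all_sig), length(sam$d))
})

test_that("nearest-centroid assignment recovers matching and mirrored profiles", {
  feats <- sprintf("f%02d", 1:10)
  centroids <- cbind(A = as.numeric(1:10), B = as.numeric(10:1))
  rownames(centroids) <- feats
  prof <- centroids[, "A"]
  names(prof) <- feats
  resA <- classify_sample(prof, centroids)
  expect_identical(resA$label, "A")
  expect_equal(resA$correlations[["A"]], 1)
  resB <- classify_sample(-prof, centroids)   # mirrored pattern -> class B
  expect_identical(resB$label, "B")
  expect_equal(resB$correlations[["B"]], 1)
  expect_error(classify_sample(prof[1:4], centroids), "< 50%")
})

test_that("held-out samples from planted clusters classify correctly", {
  co <- generate_cohort(cohort_spec(seed = 17))
  cl <- co$truth$cluster
  test_idx <- c(which(cl == 1)[1:5], which(cl == 2)[1:5])
  train <- setdiff(seq_along(cl), test_idx)
  labels <- paste0("C", cl[train])
  x_train <- co$expr[co$truth$drivers, train]
  sam <- sam_analysis(x_train, labels,
                      config = pipeline_config(sam_n_permutations = 300L))
  sig <- select_signature(sam, 0.02)
  expect_gt(nrow(sig), 5)
  ctr <- signature_centroids(x_train, labels, sig$feature)
  hits <- vapply(test_idx, function(j) {
    classify_sample(co$expr[, j], ctr)$label == paste0("C", cl[j])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
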