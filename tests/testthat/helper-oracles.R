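# Independent oracles used across tests. These deliberately re-derive the
# statistics from first principles (enumeration / explicit running sums) and
# never call the package functions they check.

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments of the combined values (tie-free inputs assumed).
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  idx_sets <- utils::combn(n, n1, simplify = FALSE)
  u_of <- function(xs, ys) sum(outer(xs, ys, `>`))
  u_obs <- u_of(x, y)
  us <- vapply(idx_sets, function(ix) u_of(pooled[ix], pooled[-ix]), numeric(1))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Brute-force single-sample enrichment score: explicit walk down the ranked
# gene list accumulating both running sums position by position.
ssgsea_brute <- function(profile, gene_set, alpha) {
  genes <- names(profile)
  ord <- order(-profile, genes)
  genes <- genes[ord]
  N <- length(genes)
  n_in <- sum(genes %in% gene_set)
  denom_in <- 0
  for (i in seq_len(N)) {
    if (genes[i] %in% gene_set) denom_in <- denom_in + (N - i + 1)^alpha
  }
  es <- 0; run_in <- 0; run_out <- 0
  for (i in seq_len(N)) {
    if (genes[i] %in% gene_set) {
      run_in <- run_in + (N - i + 1)^alpha / denom_in
    } else {
      run_out <- run_out + 1 / (N - n_in)
    }
    es <- es + (run_in - run_out)
  }
  es
}

# Adjusted Rand index between two labelings (independent implementation
# available via mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Copy-number fixture with prescribed per-sample, per-type counts.
# counts: data.frame(sample, gain, loss, loh, k_gain, k_loss, k_loh) where
# the k_ columns are the counts inside a designated kinome-like gene subset.
make_burden_calls <- function(counts, n_kinome = 531L, n_other = 23469L) {
  kin <- sprintf("K%04d", seq_len(n_kinome))
  oth <- sprintf("G%05d", seq_len(n_other))
  genes <- c(kin, oth)
  state <- matrix("NEUTRAL", length(genes), nrow(counts),
                  dimnames = list(genes, counts$sample))
  loh <- matrix(FALSE, length(genes), nrow(counts),
                dimnames = dimnames(state))
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    state[kin[seq_len(r$k_gain)], i] <- "GAIN"
    if (r$k_loss > 0) state[kin[r$k_gain + seq_len(r$k_loss)], i] <- "LOSS"
    if (r$k_loh > 0) loh[kin[seq_len(r$k_loh)], i] <- TRUE
    g <- r$gain - r$k_gain; l <- r$loss - r$k_loss; h <- r$loh - r$k_loh
    if (g > 0) state[oth[seq_len(g)], i] <- "GAIN"
    if (l > 0) state[oth[g + seq_len(l)], i] <- "LOSS"
    if (h > 0) loh[oth[seq_len(h)], i] <- TRUE
  }
  list(calls = cn_calls(state, loh), kinome = kin)
}
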