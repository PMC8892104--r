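# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive enumeration / direct definitions so they stay
# independent of the implementation paths they check.

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} (m * p_(j) / j), mapped back to input order.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(m * ps[i:m] / (i:m))
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Exact two-sided Mann-Whitney p by enumeration of all rank splits
# (tie-free data): p = 2 * min(P(U <= u), P(U >= u)) capped at 1.
bf_mwu_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  splits <- utils::combn(n, nx)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  u_all <- apply(splits, 2, u_of)
  u_obs <- u_of(seq_len(nx))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Permutation p for the Welch t by enumeration of all label assignments.
bf_welch_perm_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  welch <- function(a, b) {
    (mean(a) - mean(b)) /
      sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  }
  t_obs <- welch(x, y)
  splits <- utils::combn(n, n1)
  t_all <- apply(splits, 2, function(idx) welch(pooled[idx], pooled[-idx]))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# Upper-tail hypergeometric P(X >= k) by enumeration of all C(N, K) draws
# from a population with n successes.
bf_hyper_p <- function(k, n, N, K) {
  pop <- c(rep(1, n), rep(0, N - n))
  draws <- utils::combn(N, K)
  mean(apply(draws, 2, function(idx) sum(pop[idx])) >= k)
}

# Direct evaluation of the prevalence/abundance rule.
bf_prevalence <- function(abund, groups, thr = 0.001) {
  gl <- unique(groups)
  sapply(seq_len(nrow(abund)), function(i) {
    v <- abund[i, ]
    all1 <- all(v[groups == gl[1]] > 0)
    all2 <- all(v[groups == gl[2]] > 0)
    m1 <- mean(v[groups == gl[1]])
    m2 <- mean(v[groups == gl[2]])
    (all1 || all2) && (m1 > thr || m2 > thr)
  })
}

# Direct evaluation of the low-support gene filter.
bf_low_support <- function(counts, min_reads = 2, rule = "all") {
  keep <- apply(counts, 1, function(v) {
    if (rule == "all") any(v >= min_reads) else all(v >= min_reads)
  })
  keep
}

make_profile <- function(counts, lengths = rep(100L, nrow(counts))) {
  ids <- sprintf("g%03d", seq_len(nrow(counts)))
  rownames(counts) <- ids
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  }
  list(gene_id = ids, length = lengths, counts = counts)
}

# Two-line design over a single compartment for low-level tests.
make_two_group_design <- function(n_per_line = 10) {
  gutlink::generate_phenotypes(n_per_line, seed = 99)$design
}
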