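# Two-group differential testing for microbial features: Metastats-style
# permutation test on relative abundances (Welch t statistic, label
# permutation null) with Benjamini-Hochberg correction, and Mann-Whitney
# comparisons of functional categories with row-Z reporting.

#' Metastats-style permutation test per feature
#'
#' The statistic is the two-sample Welch t on relative abundances. The
#' null is built by permuting group labels: exhaustively over all
#' `choose(n, n1)` assignments when that count is at most `max_exhaustive`
#' (p is then the exact fraction of permuted |t| >= observed |t|,
#' including the identity), otherwise by `n_perm` Monte-Carlo draws with
#' the +1/+1 estimator `p = (1 + #{|t_perm| >= |t_obs|}) / (1 + n_perm)`,
#' so p is never 0. BH q-values are appended.
#'
#' @param abund features x samples relative-abundance matrix (pre-screened
#'   with [prevalence_abundance_filter()]).
#' @param groups group label per column (two groups, >= 3 samples each).
#' @param n_perm Monte-Carlo permutations (default 1000).
#' @param seed seed for the Monte-Carlo path.
#' @param max_exhaustive largest `choose(n, n1)` enumerated exactly.
#' @return data.frame with per-feature group means and SEs, `t`, `p`, `q`,
#'   significance `tier` (`"FDR<0.05"`, `"FDR<0.1"` or `""`) and
#'   `direction` (`"up_in_<group>"`). Constant features get p = 1.
#' @export
metastats_permutation_test <- function(abund, groups, n_perm = 1000,
                                       seed = NULL,
                                       max_exhaustive = 200000) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required")
  n1 <- sum(groups == gl[1]); n2 <- sum(groups == gl[2])
  if (n1 < 3 || n2 < 3) stop("each group needs >= 3 samples")
  n <- n1 + n2
  A <- as.matrix(abund)

  exhaustive <- choose(n, n1) <= max_exhaustive
  if (exhaustive) {
    sel <- utils::combn(n, n1)
  } else {
    if (!is.null(seed)) {
      sel <- with_seed(seed, replicate(n_perm, sample.int(n, n1)))
    } else {
      sel <- replicate(n_perm, sample.int(n, n1))
    }
  }
  K <- ncol(sel)
  # one-hot membership matrix for vectorized Welch t over all splits
  M <- matrix(0, n, K)
  M[cbind(as.vector(sel), rep(seq_len(K), each = n1))] <- 1
  S1 <- A %*% M;        S2 <- A %*% (1 - M)
  Q1 <- A^2 %*% M;      Q2 <- A^2 %*% (1 - M)
  m1 <- S1 / n1;        m2 <- S2 / n2
  v1 <- (Q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (Q2 - n2 * m2^2) / (n2 - 1)
  Tperm <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)

  obs1 <- which(groups == gl[1])
  x1 <- A[, obs1, drop = FALSE]; x2 <- A[, -obs1, drop = FALSE]
  mo1 <- rowMeans(x1); mo2 <- rowMeans(x2)
  vo1 <- apply(x1, 1, stats::var); vo2 <- apply(x2, 1, stats::var)
  t_obs <- (mo1 - mo2) / sqrt(vo1 / n1 + vo2 / n2)

  hits <- rowSums(abs(Tperm) >= abs(t_obs) - 1e-12, na.rm = TRUE)
  p <- if (exhaustive) hits / K else (1 + hits) / (1 + K)
  p[!is.finite(t_obs)] <- 1
  q <- bh_fdr(p)
  tier <- ifelse(q < 0.05, "FDR<0.05", ifelse(q < 0.1, "FDR<0.1", ""))
  data.frame(feature = rownames(A),
             mean_1 = mo1, se_1 = sqrt(vo1 / n1),
             mean_2 = mo2, se_2 = sqrt(vo2 / n2),
             t = t_obs, p = p, q = q, tier = tier,
             direction = paste0("up_in_", ifelse(mo1 >= mo2, gl[1], gl[2])),
             stringsAsFactors = FALSE, row.names = NULL) |>
    stats::setNames(c("feature", paste0("mean_", gl[1]),
                      paste0("se_", gl[1]), paste0("mean_", gl[2]),
                      paste0("se_", gl[2]), "t", "p", "q", "tier",
                      "direction"))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)` mapped
#' back to the original order, with `m` the number of non-missing
#' p-values. Missing p-values propagate as NA with a warning.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values outside [0, 1]")
  if (!all(ok)) warning("missing p-values propagate as NA")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  q
}

#' Compare functional category abundances between two groups
#'
#' Per-category Mann-Whitney U tests (significant at p < 0.05), plus the
#' row-Z matrix `(x - row mean) / row SD` used for heatmap reporting.
#'
#' @param func_abund categories x samples abundance matrix (pre-screened
#'   with [prevalence_abundance_filter()]).
#' @param groups group label per column.
#' @param scheme label recorded in the output (e.g. `"kegg"`).
#' @param p_threshold significance threshold (default 0.05).
#' @return A list with `table` (category, group means, `U`, `p`,
#'   `direction`, `significant`) and `row_z` (zero-variance rows are all
#'   zero, with a warning).
#' @export
compare_functional_categories <- function(func_abund, groups,
                                          scheme = "kegg",
                                          p_threshold = 0.05) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required")
  res <- apply(func_abund, 1, function(v) {
    mw <- mann_whitney_u(v[groups == gl[1]], v[groups == gl[2]])
    c(mw$U, mw$p)
  })
  m1 <- rowMeans(func_abund[, groups == gl[1], drop = FALSE])
  m2 <- rowMeans(func_abund[, groups == gl[2], drop = FALSE])
  tab <- data.frame(category = rownames(func_abund), scheme = scheme,
                    mean_1 = m1, mean_2 = m2,
                    U = res[1, ], p = res[2, ],
                    direction = paste0("up_in_",
                                       ifelse(m1 >= m2, gl[1], gl[2])),
                    significant = res[2, ] < p_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(tab)[3:4] <- paste0("mean_", gl)
  list(table = tab, row_z = row_z(func_abund))
}

#' Row-standardize a matrix (Z score per row)
#'
#' @param x numeric matrix.
#' @return Matrix of `(x - row mean) / row SD`; zero-variance rows become
#'   all-zero with a warning.
#' @export
row_z <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  if (any(sd == 0)) warning("zero-variance row(s); Z set to 0")
  z <- (x - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  z
}
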