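# Differential expression between lines within a compartment: a
# deliberately simplified negative-binomial Wald stage in the DESeq2
# mould - median-of-ratios size factors, method-of-moments dispersions
# optionally shrunk toward a log-linear mean-dispersion trend, a log-link
# NB GLM fit by iteratively reweighted least squares, and a two-sided Wald
# test - plus DEG calling at the |log2FC| > 1.5 and FDR < 0.05 thresholds,
# qPCR delta-delta-Ct concordance, and hypergeometric pathway enrichment.

#' Median-of-ratios size factors
#'
#' `factor_j = median_g(count_gj / geometric mean_g)` over genes with
#' nonzero counts in all samples; when no such gene exists the geometric
#' means are taken over positive counts only, with a warning. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts genes x samples non-negative integer matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  lmat <- log(counts)
  lg <- rowMeans(lmat)
  ok <- is.finite(lg)
  if (!any(ok)) {
    warning("no gene has positive counts in all samples; ",
            "using positive-count geometric means")
    lmat[!is.finite(lmat)] <- NA
    lg <- rowMeans(lmat, na.rm = TRUE)
    ok <- is.finite(lg) & rowSums(counts > 0) > 1
    if (!any(ok)) stop("no usable genes for size-factor estimation")
  }
  lsf <- apply(lmat[ok, , drop = FALSE] - lg[ok], 2,
               stats::median, na.rm = TRUE)
  if (any(!is.finite(lsf))) stop("size factors are not estimable")
  sf <- exp(lsf - mean(lsf))
  stats::setNames(sf, colnames(counts))
}

#' Method-of-moments NB dispersions with optional trend shrinkage
#'
#' Per gene, on size-factor-normalized counts: `alpha = (s^2 - mu *
#' mean(1/sf)) / mu^2` with `s^2` the pooled within-group variance,
#' floored at `1e-8`. With `shrink = TRUE` (default) the log dispersion is
#' shrunk with weight `shrink_weight` toward a log-linear fit of
#' dispersion on mean expression.
#'
#' @param counts genes x samples matrix.
#' @param groups two-group label per sample.
#' @param sf size factors (default from [size_factors()]).
#' @param shrink shrink toward the mean-dispersion trend.
#' @param shrink_weight weight on the trend (default 0.5).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersions <- function(counts, groups, sf = size_factors(counts),
                                 shrink = TRUE, shrink_weight = 0.5) {
  y <- sweep(counts, 2, sf, `/`)
  groups <- as.character(groups)
  gl <- unique(groups)
  mu <- rowMeans(y)
  ss <- 0; df <- 0
  for (g in gl) {
    yg <- y[, groups == g, drop = FALSE]
    ss <- ss + rowSums((yg - rowMeans(yg))^2)
    df <- df + ncol(yg) - 1
  }
  v <- ss / df
  alpha <- pmax((v - mu * mean(1 / sf)) / mu^2, 1e-8)
  alpha[!is.finite(alpha)] <- 1e-8
  if (shrink) {
    use <- mu > 0 & alpha > 1e-8
    if (sum(use) >= 10) {
      fit <- stats::lm(log(alpha[use]) ~ log(mu[use]))
      trend <- exp(stats::predict(fit, list(`log(mu[use])` = log(mu))))
      trend <- exp(cbind(1, log(pmax(mu, 1e-8))) %*% stats::coef(fit))[, 1]
      alpha <- exp((1 - shrink_weight) * log(alpha) +
                     shrink_weight * log(pmax(trend, 1e-8)))
    }
  }
  stats::setNames(alpha, rownames(counts))
}

#' Negative-binomial Wald test per gene
#'
#' Fits, per gene, a log-link NB GLM with intercept and line coefficient
#' (offset = log size factor) by iteratively reweighted least squares at
#' the gene's plug-in dispersion, then tests the line coefficient with a
#' two-sided Wald test. The sign convention is lean vs fat: positive
#' log2FC = higher in the lean line. BH is applied over genes with
#' nonzero total count; all-zero genes report NA and are excluded from the
#' correction.
#'
#' @param counts genes x samples matrix for one compartment.
#' @param groups line label per sample (`"lean"` / `"fat"`, or any two
#'   labels - the first level alphabetically unmatched to lean/fat is the
#'   reference).
#' @param sf size factors.
#' @param dispersions per-gene dispersions (default
#'   [estimate_dispersions()]).
#' @param ... passed to [estimate_dispersions()].
#' @return data.frame(`gene_id`, `base_mean`, `log2fc`, `se`, `stat`,
#'   `p`, `q`).
#' @export
nb_fit_and_test <- function(counts, groups, sf = size_factors(counts),
                            dispersions = NULL, ...) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required")
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples")
  if (min(table(groups)) < 3) {
    warning("fewer than 3 samples in a group; estimates will be unstable")
  }
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, groups, sf, ...)
  }
  # x = 1 for the lean line so the coefficient is lean-vs-fat
  lean_label <- if ("lean" %in% gl) "lean" else gl[1]
  x <- as.numeric(groups == lean_label)
  fit <- nb_irls(counts, x, sf, dispersions)
  keep <- rowSums(counts) > 0
  # t reference with n - 2 df rather than normal: the plug-in dispersions
  # are estimated from the same few samples, and the normal reference is
  # visibly anticonservative at n = 10 + 10
  p <- ifelse(keep,
              2 * stats::pt(-abs(fit$beta1 / fit$se1), ncol(counts) - 2),
              NA)
  q <- bh_fdr(p)
  data.frame(gene_id = rownames(counts),
             base_mean = rowMeans(sweep(counts, 2, sf, `/`)),
             log2fc = ifelse(keep, fit$beta1 / log(2), NA),
             se = ifelse(keep, fit$se1 / log(2), NA),
             stat = ifelse(keep, fit$beta1 / fit$se1, NA),
             p = p, q = q, stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized-across-genes IRLS for the two-group NB GLM with log link and
# offsets. Weights w = mu / (1 + alpha * mu); the 2x2 normal equations are
# solved in closed form per gene.
nb_irls <- function(counts, x, sf, alpha, max_iter = 50, tol = 1e-10) {
  G <- nrow(counts); n <- ncol(counts)
  off <- matrix(log(sf), G, n, byrow = TRUE)
  n1 <- sum(x == 1); n0 <- sum(x == 0)
  m1 <- rowSums(sweep(counts[, x == 1, drop = FALSE], 2,
                      sf[x == 1], `/`)) / n1
  m0 <- rowSums(sweep(counts[, x == 0, drop = FALSE], 2,
                      sf[x == 0], `/`)) / n0
  pseudo <- pmax(rowMeans(counts), 1) * 1e-3 + 1e-8
  beta0 <- log(pmax(m0, pseudo))
  beta1 <- log(pmax(m1, pseudo)) - beta0
  xm <- matrix(x, G, n, byrow = TRUE)
  for (it in seq_len(max_iter)) {
    eta <- beta0 + beta1 %o% rep(1, n) * xm + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (counts - mu) / mu
    Sw <- rowSums(w); Swx <- rowSums(w * xm); Swxx <- Swx
    Swz <- rowSums(w * z); Swxz <- rowSums(w * xm * z)
    det <- Sw * Swxx - Swx^2
    det[det <= 0] <- NA
    b1 <- (Sw * Swxz - Swx * Swz) / det
    b0 <- (Swxx * Swz - Swx * Swxz) / det
    b1 <- pmin(pmax(b1, -30), 30)
    b0 <- pmin(pmax(b0, -50), 50)
    delta <- pmax(abs(b1 - beta1), abs(b0 - beta0), na.rm = TRUE)
    conv <- all(delta < tol, na.rm = TRUE)
    beta1 <- ifelse(is.na(b1), beta1, b1)
    beta0 <- ifelse(is.na(b0), beta0, b0)
    if (conv) break
  }
  eta <- beta0 + beta1 %o% rep(1, n) * xm + off
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  Sw <- rowSums(w); Swx <- rowSums(w * xm)
  det <- Sw * Swx - Swx^2
  se1 <- sqrt(Sw / pmax(det, .Machine$double.eps))
  list(beta0 = beta0, beta1 = beta1, se1 = se1)
}

#' Call differentially expressed genes
#'
#' A gene is a DEG iff `q < q_threshold` AND `|log2FC| > lfc_threshold`
#' (both strict, matching the study's rule: FDR less than 0.05 and
#' absolute log2 fold change more than 1.5).
#'
#' @param results data.frame from [nb_fit_and_test()], or a named list of
#'   them (one per compartment).
#' @param lfc_threshold log2 fold-change threshold (default 1.5).
#' @param q_threshold FDR threshold (default 0.05).
#' @return For a single result: the data.frame with an `is_deg` column
#'   plus attributes `n_up` / `n_down`. For a list: a list of flagged
#'   data.frames with attribute `intersection` - the cross-compartment
#'   common-DEG count table.
#' @export
call_degs <- function(results, lfc_threshold = 1.5, q_threshold = 0.05) {
  flag <- function(df) {
    df$is_deg <- !is.na(df$q) & df$q < q_threshold &
      abs(df$log2fc) > lfc_threshold
    attr(df, "n_up") <- sum(df$is_deg & df$log2fc > 0)
    attr(df, "n_down") <- sum(df$is_deg & df$log2fc < 0)
    df
  }
  if (is.data.frame(results)) return(flag(results))
  out <- lapply(results, flag)
  sets <- lapply(out, function(df) df$gene_id[df$is_deg])
  common_all <- Reduce(intersect, sets)
  inter <- data.frame(compartments = c(names(sets), "all"),
                      n_deg = c(lengths(sets), length(common_all)),
                      stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "intersection") <- inter
  out
}

#' qPCR log2 fold change by the 2^-ddCt method, with RNA-seq concordance
#'
#' Per gene: `dCt = Ct_target - Ct_ref` per sample, `ddCt =
#' mean dCt(group2) - mean dCt(group1)`, and the returned qPCR log2 fold
#' change is `-ddCt` (so the fold change is `2^-ddCt`, group2 vs group1).
#'
#' @param ct genes x samples matrix of target Ct values.
#' @param ct_ref reference-gene Ct per sample (same reference for all).
#' @param groups two-group label per sample; `levels` order fixes which
#'   group is the baseline (group1 = first unique label).
#' @param rnaseq_log2fc optional named vector of RNA-seq log2FCs for the
#'   same genes and comparison; enables concordance statistics.
#' @return A list with `log2fc` (named, qPCR scale) and, when RNA-seq
#'   values are supplied, `pearson_r` and `r_squared` from the pairwise
#'   correlation and linear regression of the two log2FC vectors.
#' @export
ddct_log2fc <- function(ct, ct_ref, groups, rnaseq_log2fc = NULL) {
  ct <- rbind(ct)
  if (length(ct_ref) != ncol(ct) || any(!is.finite(ct_ref))) {
    stop("finite reference Ct required for every sample")
  }
  if (any(!is.finite(ct))) stop("Ct values must be finite")
  groups <- as.character(groups)
  gl <- unique(groups)
  dct <- sweep(ct, 2, ct_ref)
  ddct <- rowMeans(dct[, groups == gl[2], drop = FALSE]) -
    rowMeans(dct[, groups == gl[1], drop = FALSE])
  out <- list(log2fc = -ddct)
  if (!is.null(rnaseq_log2fc)) {
    v <- rnaseq_log2fc[rownames(ct)]
    out$pearson_r <- stats::cor(out$log2fc, v)
    out$r_squared <- summary(stats::lm(v ~ out$log2fc))$r.squared
  }
  out
}

#' Hypergeometric pathway enrichment with Rich factor
#'
#' Upper-tail hypergeometric test `P(X >= k)` with population `N` (the
#' background), `n` successes (genes annotated to the pathway), `K` draws
#' (the DEGs). The Rich factor is `k / n`, the proportion of a pathway's
#' annotated genes that are differentially expressed. BH q-values are
#' reported alongside; significance defaults to raw p < 0.05.
#'
#' @param deg_set character vector of DEG ids (subset of the background).
#' @param background_set character vector of background gene ids.
#' @param pathway_map data.frame(`gene_id`, `pathway_id`, optionally
#'   `pathway_name`).
#' @param p_threshold significance threshold (default 0.05).
#' @param use_q use BH q instead of raw p for the significance flag.
#' @return data.frame(`pathway_id`, `pathway_name`, `k`, `K`, `n`, `N`,
#'   `rich_factor`, `p`, `q`, `significant`), sorted by p.
#' @export
pathway_enrichment <- function(deg_set, background_set, pathway_map,
                               p_threshold = 0.05, use_q = FALSE) {
  if (!all(deg_set %in% background_set)) {
    stop("deg_set must be a subset of background_set")
  }
  if (!length(deg_set)) {
    warning("empty DEG set; no enrichment computed")
    return(data.frame())
  }
  map <- pathway_map[pathway_map$gene_id %in% background_set, ]
  N <- length(unique(background_set))
  K <- length(unique(deg_set))
  paths <- split(map$gene_id, map$pathway_id)
  rows <- lapply(names(paths), function(pw) {
    pg <- unique(paths[[pw]])
    n <- length(pg)
    k <- length(intersect(pg, deg_set))
    data.frame(pathway_id = pw,
               pathway_name = if ("pathway_name" %in% names(map))
                 map$pathway_name[match(pw, map$pathway_id)] else pw,
               k = k, K = K, n = n, N = N,
               rich_factor = k / n,
               p = stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- (if (use_q) out$q else out$p) < p_threshold
  out <- out[order(out$p, out$pathway_id), ]
  rownames(out) <- NULL
  out
}
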