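# Community profile: alpha diversity, two-group rank tests, supervised
# ordination (PLS-DA) and composition summaries.

#' Per-sample alpha diversity
#'
#' Richness is the number of features with abundance > 0; Shannon is
#' `-sum(p * log(p))` over the nonzero renormalized proportions. Natural
#' log by default (the ecology convention); configurable via `base`.
#'
#' @param abund features x samples abundance matrix.
#' @param base logarithm base (default `exp(1)`).
#' @return data.frame(`sample_id`, `richness`, `shannon`). All-zero
#'   samples yield richness 0 and Shannon 0 with a warning.
#' @export
alpha_diversity <- function(abund, base = exp(1)) {
  if (any(abund < 0)) stop("abundances must be non-negative")
  tot <- colSums(abund)
  if (any(tot == 0)) warning("all-zero sample(s); diversity set to 0")
  shannon <- vapply(seq_len(ncol(abund)), function(j) {
    p <- abund[, j]
    p <- p[p > 0]
    if (!length(p)) return(0)
    p <- p / sum(p)
    -sum(p * log(p, base = base))
  }, numeric(1))
  data.frame(sample_id = colnames(abund),
             richness = colSums(abund > 0),
             shannon = shannon, stringsAsFactors = FALSE, row.names = NULL)
}

#' Mann-Whitney U test
#'
#' Exact p by enumeration of rank arrangements when `n_x + n_y <= 16` and
#' the pooled data are tie-free; otherwise the normal approximation with
#' tie and continuity corrections. Two-sided by default.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list with `U` (the statistic for `x`) and `p`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (length(x) < 2 || length(y) < 2) stop("both groups need >= 2 values")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("constant pooled data; p = 1")
    return(list(U = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && length(pooled) <= 16
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fit a PLS-DA ordination of community composition on class labels
#'
#' NIPALS partial least squares against the one-hot class matrix with
#' sequential deflation, plus cross-validated accuracy of a nearest
#' class-centroid rule in score space. Features are column-centered and,
#' by default, unit-variance scaled. Sign convention: each component's
#' X-loading vector has a non-negative sum (flipped otherwise), making
#' scores reproducible.
#'
#' @param abund features x samples abundance matrix.
#' @param labels class label per sample (two or more classes).
#' @param n_components number of latent components (default 2).
#' @param cv_folds number of cross-validation folds; `nrow` samples (the
#'   default `NULL`) gives leave-one-out.
#' @param scale. unit-variance scale features before fitting.
#' @return A list of class `gut_plsda` with `scores` (samples x
#'   components), `loadings`, `weights`, `accuracy` (cross-validated) and
#'   `labels`.
#' @export
plsda_fit <- function(abund, labels, n_components = 2, cv_folds = NULL,
                      scale. = TRUE) {
  X <- t(abund)
  labels <- factor(labels)
  if (any(table(labels) < 2)) stop(">= 2 samples per class required")
  if (n_components >= min(nrow(X) - 1, ncol(X))) {
    stop("n_components must be < min(samples - 1, features)")
  }
  fit <- nipals_pls(X, labels, n_components, scale.)
  n <- nrow(X)
  folds <- if (is.null(cv_folds) || cv_folds >= n) seq_len(n) else
    rep_len(seq_len(cv_folds), n)
  pred <- character(n)
  for (f in unique(folds)) {
    test <- which(folds == f)
    sub <- nipals_pls(X[-test, , drop = FALSE], labels[-test],
                      n_components, scale.)
    Xc <- sweep(X[test, , drop = FALSE], 2, sub$center)
    if (scale.) Xc <- sweep(Xc, 2, sub$scale, `/`)
    Tt <- Xc %*% sub$rotation
    cent <- apply(sub$scores, 2, tapply, labels[-test], mean)
    d2 <- outer(rowSums(Tt^2), rowSums(cent^2), `+`) -
      2 * Tt %*% t(cent)
    pred[test] <- colnames(d2)[apply(d2, 1, which.min)]
  }
  structure(list(scores = fit$scores, loadings = fit$loadings,
                 weights = fit$weights,
                 accuracy = mean(pred == as.character(labels)),
                 labels = labels),
            class = "gut_plsda")
}

# NIPALS PLS2 on a one-hot response; returns scores/loadings/weights and
# the projection rotation W (P'W)^-1 used to project new samples.
nipals_pls <- function(X, labels, n_components, scale.) {
  center <- colMeans(X)
  X <- sweep(X, 2, center)
  scl <- rep(1, ncol(X))
  if (scale.) {
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    X <- sweep(X, 2, scl, `/`)
  }
  Y <- stats::model.matrix(~ 0 + labels)
  Y <- scale(Y, scale = FALSE)
  n <- nrow(X)
  Ts <- matrix(0, n, n_components)
  P <- matrix(0, ncol(X), n_components)
  W <- matrix(0, ncol(X), n_components)
  for (h in seq_len(n_components)) {
    u <- Y[, which.max(colSums(Y^2))]
    for (it in 1:200) {
      w <- crossprod(X, u)
      w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      q <- crossprod(Y, tt) / sum(tt^2)
      u_new <- Y %*% q / sum(q^2)
      if (sum((u_new - u)^2) < 1e-12 * sum(u^2)) { u <- u_new; break }
      u <- u_new
    }
    p <- crossprod(X, tt) / sum(tt^2)
    if (sum(p) < 0) { p <- -p; w <- -w; tt <- -tt; q <- -q }
    X <- X - tcrossprod(tt, p)
    Y <- Y - tcrossprod(tt, q)
    Ts[, h] <- tt; P[, h] <- p; W[, h] <- w
  }
  colnames(Ts) <- colnames(P) <- colnames(W) <-
    paste0("comp", seq_len(n_components))
  rotation <- W %*% solve(crossprod(P, W))
  list(scores = Ts, loadings = P, weights = W, rotation = rotation,
       center = center, scale = scl)
}

#' @export
print.gut_plsda <- function(x, ...) {
  cat("PLS-DA ordination: ", ncol(x$scores), " components, ",
      nlevels(x$labels), " classes\n", sep = "")
  cat("cross-validated nearest-centroid accuracy: ",
      format(x$accuracy, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Firmicutes / Bacteroidetes ratio per sample
#'
#' @param phylum_abund phylum-level abundance matrix containing Firmicutes
#'   and Bacteroidetes rows (matched case-insensitively).
#' @return Named numeric vector of per-sample ratios; samples with zero
#'   Bacteroidetes get `Inf` with a warning.
#' @export
fb_ratio <- function(phylum_abund) {
  rn <- tolower(rownames(phylum_abund))
  fi <- match("firmicutes", rn)
  ba <- match("bacteroidetes", rn)
  if (is.na(fi) || is.na(ba)) {
    stop("phylum matrix must contain Firmicutes and Bacteroidetes rows")
  }
  f <- phylum_abund[fi, ]
  b <- phylum_abund[ba, ]
  if (any(b == 0)) warning("zero Bacteroidetes abundance; ratio is Inf")
  f / b
}

#' Top-n composition summary per line and compartment
#'
#' Features are ranked by overall mean abundance (ties broken by feature id
#' lexical order); per-group means are reported with the remainder lumped
#' into an `"other"` row.
#'
#' @param abund features x samples abundance matrix (typically species).
#' @param design sample design aligned to the columns.
#' @param n number of named features (default 10).
#' @return data.frame(`feature`, `line`, `compartment`, `mean_abundance`).
#' @export
top_n_composition <- function(abund, design, n = 10) {
  check_design(design)
  design <- design[match(colnames(abund), design$sample_id), ]
  overall <- rowMeans(abund)
  ord <- order(-overall, rownames(abund))
  top <- rownames(abund)[ord][seq_len(min(n, nrow(abund)))]
  out <- do.call(rbind, lapply(split(seq_len(ncol(abund)),
                                     list(design$line, design$compartment),
                                     sep = "|"), function(idx) {
    if (!length(idx)) return(NULL)
    m <- rowMeans(abund[, idx, drop = FALSE])
    data.frame(feature = c(top, "other"),
               line = design$line[idx[1]],
               compartment = design$compartment[idx[1]],
               mean_abundance = c(m[top], sum(m) - sum(m[top])),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
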