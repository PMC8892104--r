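# Multi-omics association cascade: select abdominal-fat relevant traits
# (AFRT), build weighted co-expression modules (soft-threshold adjacency,
# topological overlap, eigengenes), screen modules/genes by Pearson
# correlation with AFRT, screen microbial species by Spearman correlation
# with AFRT, and correlate AFRT-correlated DEGs with AFRT-correlated
# species per compartment (p < 0.05 in the small intestine, p < 0.01 in
# the ceca).

#' Correlation with a t-approximation p-value
#'
#' Pearson on raw values, or Spearman as Pearson on mid-ranks (average
#' ranks for ties). Two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))`
#' on `n - 2` df; `|r| = 1` gives p = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 4), finite.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r` and `p` (both NA when either vector has zero
#'   variance).
#' @export
correlation_with_p <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("n >= 4 required")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1 - 1e-12) return(list(r = sign(r), p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Columns of X against y; returns a matrix with r and p rows.
cor_matrix_with_p <- function(X, y, method) {
  out <- apply(X, 2, function(col) {
    if (stats::sd(col) == 0) return(c(NA_real_, NA_real_))
    cp <- correlation_with_p(col, y, method)
    c(cp$r, cp$p)
  })
  rownames(out) <- c("r", "p")
  out
}

#' Select abdominal-fat relevant traits
#'
#' Each serum index is tested (Pearson, two-sided) against both AFW and
#' AFP across birds; a trait is an AFRT if either p < `p_threshold`.
#' AFW and AFP themselves are always included as anchor traits. BW is not
#' a serum index and is not screened.
#'
#' @param phenotypes phenotype table (one row per bird, AFW and AFP
#'   present).
#' @param p_threshold significance threshold (default 0.05).
#' @return A list with `traits` (selected, anchors first) and `table`
#'   (per-trait r and p against AFW and AFP). Constant traits are
#'   excluded with a warning.
#' @export
select_afrt <- function(phenotypes, p_threshold = 0.05) {
  if (!all(c("AFW", "AFP") %in% names(phenotypes))) {
    stop("phenotypes must contain AFW and AFP")
  }
  if (nrow(phenotypes) < 6) stop(">= 6 birds required")
  serum <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric,
                                            logical(1))],
                   c("AFW", "AFP", "BW"))
  rows <- lapply(serum, function(tr) {
    v <- phenotypes[[tr]]
    if (stats::sd(v) == 0) {
      warning("constant trait excluded: ", tr)
      return(NULL)
    }
    a <- correlation_with_p(v, phenotypes$AFW, "pearson")
    b <- correlation_with_p(v, phenotypes$AFP, "pearson")
    data.frame(trait = tr, r_afw = a$r, p_afw = a$p, r_afp = b$r,
               p_afp = b$p,
               selected = (!is.na(a$p) && a$p < p_threshold) ||
                 (!is.na(b$p) && b$p < p_threshold),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(traits = c("AFW", "AFP", tab$trait[tab$selected]), table = tab)
}

#' Choose the soft-threshold power by the scale-free criterion
#'
#' For each candidate power the unsigned adjacency is `|cor|^beta`;
#' connectivity `k_i` is its row sum. The scale-free fit R^2 is the
#' squared correlation between `log10(freq)` and `log10(mean k)` over
#' connectivity bins. The smallest power reaching `rsq_cut` is chosen,
#' else the power with maximal R^2 (noted via `message()`).
#'
#' @param expr samples x genes expression matrix (>= 8 samples).
#' @param powers candidate powers.
#' @param rsq_cut scale-free R^2 target (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @return A list with `power` and `table` (power, rsq, mean_k).
#' @export
pick_soft_power <- function(expr, powers = c(1:10, 12, 14, 16),
                            rsq_cut = 0.8, n_bins = 10) {
  if (nrow(expr) < 8) stop(">= 8 samples required")
  ac <- abs(stats::cor(expr))
  diag(ac) <- 0
  tab <- do.call(rbind, lapply(powers, function(b) {
    k <- colSums(ac^b)
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, brk, include.lowest = TRUE)
    freq <- tabulate(bin, n_bins)
    mk <- tapply(k, bin, mean)
    keep <- freq > 0 & !is.na(mk) & mk > 0
    if (sum(keep) < 3) stop("fewer than 3 nonempty connectivity bins")
    rsq <- stats::cor(log10(freq[keep]), log10(mk[keep]))^2
    data.frame(power = b, rsq = rsq, mean_k = mean(k))
  }))
  hit <- which(tab$rsq >= rsq_cut)
  if (length(hit)) {
    power <- tab$power[hit[1]]
  } else {
    power <- tab$power[which.max(tab$rsq)]
    message("no power reached scale-free R^2 >= ", rsq_cut,
            "; using power ", power, " (max R^2 = ",
            format(max(tab$rsq), digits = 3), ")")
  }
  list(power = power, table = tab)
}

#' Topological overlap matrix of an unsigned adjacency
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' unit diagonal; entries lie in `[0, 1]` for adjacencies in `[0, 1]`.
#'
#' @param adjacency symmetric matrix with entries in `[0, 1]` (diagonal
#'   ignored).
#' @return The TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a
  k <- colSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom
}

#' Build weighted co-expression modules
#'
#' Unsigned adjacency `|cor|^power`, topological overlap, average-linkage
#' hierarchical clustering on `1 - TOM`, static tree cut, grey-labelling
#' of undersized clusters, eigengene computation (first principal
#' component of the module's standardized expression, sign-oriented to
#' correlate positively with the module's mean expression profile), and
#' iterative merging of modules whose eigengenes correlate above
#' `1 - merge_height`.
#'
#' @param expr samples x genes matrix (zero-variance genes are dropped
#'   with a warning).
#' @param power soft-threshold power (e.g. from [pick_soft_power()]).
#' @param min_module_size smallest retained module (default 30).
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. correlation > 0.75).
#' @param kme_min module-membership floor for the kME refinement pass:
#'   after the initial cut and eigengene merge, every gene is assigned to
#'   the module whose eigengene it matches best, or to grey when no
#'   |kME| reaches this floor (the standard cleanup step of weighted
#'   co-expression practice).
#' @param cut_height static tree-cut height on the 1 - TOM dendrogram, or
#'   `"auto"` (default): scan merge-height quantiles and cut where the
#'   number of clusters of at least `min_module_size` genes is maximal
#'   (highest such cut on ties). The TOM scale shifts with the chosen
#'   soft power, so no single fixed height suits all inputs.
#' @return A list of class `gut_modules`: `membership` (gene -> module,
#'   `"grey"` = unassigned), `eigengenes` (samples x modules, unit
#'   variance), `kme` (gene correlation with each eigengene), `power`,
#'   `sizes`.
#' @export
build_modules <- function(expr, power, min_module_size = 30,
                          merge_height = 0.25, cut_height = "auto",
                          kme_min = 0.5) {
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s) dropped")
    expr <- expr[, sds > 0, drop = FALSE]
  }
  if (ncol(expr) < min_module_size) stop("fewer genes than min_module_size")
  A <- abs(stats::cor(expr))^power
  tom <- tom_similarity(A)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (identical(cut_height, "auto")) {
    cand <- unique(stats::quantile(hc$height, seq(0.5, 0.998, by = 0.002)))
    n_big <- vapply(cand, function(h) {
      sum(table(stats::cutree(hc, h = h)) >= min_module_size)
    }, numeric(1))
    cut_height <- max(cand[n_big == max(n_big)])
  }
  cl <- stats::cutree(hc, h = cut_height)
  membership <- stats::setNames(rep("grey", ncol(expr)), colnames(expr))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  for (i in seq_along(keep)) {
    membership[cl == as.integer(keep[i])] <- paste0("M", i)
  }

  eigengene <- function(genes) {
    Z <- scale(expr[, genes, drop = FALSE])
    e <- svd(Z, nu = 1, nv = 0)$u[, 1]
    if (stats::cor(e, rowMeans(Z)) < 0) e <- -e
    e / stats::sd(e)
  }
  mods <- setdiff(unique(membership), "grey")
  egs <- vapply(mods, function(m) eigengene(names(membership)[
    membership == m]), numeric(nrow(expr)))
  # iterative eigengene merging
  while (length(mods) > 1) {
    cc <- stats::cor(egs)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= 1 - merge_height) break
    m1 <- mods[mx[1]]; m2 <- mods[mx[2]]
    membership[membership == m2] <- m1
    mods <- setdiff(mods, m2)
    egs <- egs[, mods, drop = FALSE]
    egs[, m1] <- eigengene(names(membership)[membership == m1])
  }
  # kME refinement (standard module cleanup): every gene goes to the
  # module whose eigengene it matches best, or to grey when no |kME|
  # reaches kme_min; eigengenes are then recomputed
  for (pass in 1:2) {
    if (!length(mods)) break
    kme <- stats::cor(expr, egs[, mods, drop = FALSE])
    best <- mods[max.col(abs(kme), ties.method = "first")]
    best[apply(abs(kme), 1, max) < kme_min] <- "grey"
    names(best) <- colnames(expr)
    sizes <- table(best[best != "grey"])
    best[best %in% names(sizes)[sizes < min_module_size]] <- "grey"
    if (identical(unname(best), unname(membership))) break
    membership <- best
    mods <- intersect(mods, unique(membership))
    if (!length(mods)) break
    egs <- vapply(mods, function(m) eigengene(names(membership)[
      membership == m]), numeric(nrow(expr)))
  }
  if (!length(mods)) stop("no module survived refinement")

  # relabel by decreasing size for stable naming
  ord <- names(sort(table(membership[membership != "grey"]),
                    decreasing = TRUE))
  relabel <- stats::setNames(paste0("M", seq_along(ord)), ord)
  membership[membership != "grey"] <- relabel[membership[
    membership != "grey"]]
  colnames(egs) <- relabel[colnames(egs)]
  egs <- egs[, order(colnames(egs)), drop = FALSE]
  rownames(egs) <- rownames(expr)
  kme <- stats::cor(expr, egs)
  structure(list(membership = membership, eigengenes = egs, kme = kme,
                 power = power,
                 sizes = table(membership)),
            class = "gut_modules")
}

#' @export
print.gut_modules <- function(x, ...) {
  cat("Co-expression modules (power ", x$power, "):\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' Screen modules and genes for AFRT correlation
#'
#' Step 1: each module eigengene is tested (Pearson) against every AFRT
#' trait; a module is kept if any p < `p_threshold`. Step 2: genes inside
#' kept modules are kept if their expression has Pearson p <
#' `p_threshold` against any AFRT trait. Hub genes additionally have
#' `|kME| >= hub_kme` for their own module.
#'
#' @param modules `gut_modules` from [build_modules()].
#' @param expr samples x genes matrix (same samples as the modules).
#' @param traits samples x traits matrix/data.frame of AFRT trait values
#'   (bird-level values repeated per sample).
#' @param p_threshold significance threshold (default 0.05).
#' @param hub_kme hub-gene module-membership threshold (default 0.8).
#' @return A list with `modules_selected`, `module_trait_p`, `genes`
#'   (data.frame gene/module/min_p/hub) and `gene_set`.
#' @export
screen_genes <- function(modules, expr, traits, p_threshold = 0.05,
                         hub_kme = 0.8) {
  traits <- as.matrix(traits)
  stopifnot(nrow(traits) == nrow(expr))
  egs <- modules$eigengenes
  ptab <- matrix(NA_real_, ncol(egs), ncol(traits),
                 dimnames = list(colnames(egs), colnames(traits)))
  for (tr in colnames(traits)) {
    ptab[, tr] <- cor_matrix_with_p(egs, traits[, tr], "pearson")["p", ]
  }
  kept <- rownames(ptab)[apply(ptab, 1, function(p)
    any(p < p_threshold, na.rm = TRUE))]
  genes <- names(modules$membership)[modules$membership %in% kept]
  rows <- lapply(genes, function(g) {
    pv <- vapply(colnames(traits), function(tr) {
      correlation_with_p(expr[, g], traits[, tr], "pearson")$p
    }, numeric(1))
    m <- modules$membership[g]
    data.frame(gene = g, module = m, min_p = min(pv, na.rm = TRUE),
               kme = modules$kme[g, m],
               stringsAsFactors = FALSE)
  })
  gt <- do.call(rbind, rows)
  if (is.null(gt)) {
    gt <- data.frame(gene = character(), module = character(),
                     min_p = numeric(), kme = numeric())
  }
  gt <- gt[gt$min_p < p_threshold, , drop = FALSE]
  gt$hub <- abs(gt$kme) >= hub_kme
  rownames(gt) <- NULL
  list(modules_selected = kept, module_trait_p = ptab, genes = gt,
       gene_set = gt$gene)
}

#' Screen microbial species for AFRT correlation
#'
#' A species is kept when its Spearman correlation with any AFRT trait
#' has p < `p_threshold`. For the ceca, `restrict_to` limits the screen
#' to the line-differential species (the study's rule for the
#' species-rich cecal community).
#'
#' @param species_abund species x samples abundance matrix.
#' @param traits samples x traits matrix of AFRT trait values.
#' @param p_threshold significance threshold (default 0.05).
#' @param restrict_to optional species id subset to screen within.
#' @return A list with `species` (kept ids) and `table` (species,
#'   best trait, rho, p).
#' @export
screen_microbes <- function(species_abund, traits, p_threshold = 0.05,
                            restrict_to = NULL) {
  traits <- as.matrix(traits)
  stopifnot(ncol(species_abund) == nrow(traits))
  if (!is.null(restrict_to)) {
    keep <- intersect(rownames(species_abund), restrict_to)
    if (!length(keep)) {
      warning("restrict_to is disjoint from the abundance matrix")
      return(list(species = character(0),
                  table = data.frame(species = character(),
                                     trait = character(), rho = numeric(),
                                     p = numeric())))
    }
    species_abund <- species_abund[keep, , drop = FALSE]
  }
  rows <- lapply(rownames(species_abund), function(sp) {
    v <- species_abund[sp, ]
    if (stats::sd(v) == 0) return(NULL)
    res <- vapply(colnames(traits), function(tr) {
      cp <- correlation_with_p(v, traits[, tr], "spearman")
      c(cp$r, cp$p)
    }, numeric(2))
    best <- which.min(res[2, ])
    data.frame(species = sp, trait = colnames(traits)[best],
               rho = res[1, best], p = res[2, best],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(species = character(), trait = character(),
                      rho = numeric(), p = numeric())
  }
  rownames(tab) <- NULL
  list(species = tab$species[!is.na(tab$p) & tab$p < p_threshold],
       table = tab)
}

#' Correlate AFRT-correlated DEGs with AFRT-correlated species
#'
#' For every (species, gene) pair with the gene both AFRT-correlated and
#' a DEG, the Spearman correlation across birds is computed; records are
#' kept below the compartment's threshold: p < 0.05 in the small
#' intestine, p < 0.01 in the ceca.
#'
#' @param species_set AFRT-correlated species ids.
#' @param gene_set AFRT-correlated gene ids.
#' @param deg data.frame with `gene_id`, `log2fc`, `is_deg` (from
#'   [call_degs()]).
#' @param species_abund species x samples matrix for the compartment.
#' @param expr samples x genes expression matrix (same samples, same
#'   order; mismatched sample names are a hard error).
#' @param compartment compartment name; sets the default threshold.
#' @param p_threshold override the per-compartment default.
#' @param species_direction optional named vector of species line
#'   directions (e.g. from the Metastats table) copied onto the records.
#' @return data.frame of association records (compartment, species, gene,
#'   rho, p, gene_log2fc, species_direction), sorted by species then p,
#'   with attribute `p_threshold`.
#' @export
cross_omic_associations <- function(species_set, gene_set, deg,
                                    species_abund, expr, compartment,
                                    p_threshold = NULL,
                                    species_direction = NULL) {
  if (!identical(colnames(species_abund), rownames(expr))) {
    miss <- c(setdiff(colnames(species_abund), rownames(expr)),
              setdiff(rownames(expr), colnames(species_abund)))
    stop("omics layers misaligned on samples: ",
         paste(unique(miss), collapse = ", "))
  }
  if (is.null(p_threshold)) {
    p_threshold <- if (compartment == "ceca") 0.01 else 0.05
  }
  degs <- deg$gene_id[deg$is_deg]
  genes <- intersect(gene_set, degs)
  species <- intersect(species_set, rownames(species_abund))
  rows <- list()
  for (sp in species) {
    for (g in genes) {
      cp <- correlation_with_p(species_abund[sp, ], expr[, g], "spearman")
      if (!is.na(cp$p) && cp$p < p_threshold) {
        rows[[length(rows) + 1]] <- data.frame(
          compartment = compartment, species = sp, gene = g,
          rho = cp$r, p = cp$p,
          gene_log2fc = deg$log2fc[match(g, deg$gene_id)],
          species_direction = if (!is.null(species_direction))
            species_direction[sp] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(compartment = character(), species = character(),
               gene = character(), rho = numeric(), p = numeric(),
               gene_log2fc = numeric(), species_direction = character())
  out <- out[order(out$species, out$p), ]
  rownames(out) <- NULL
  attr(out, "p_threshold") <- p_threshold
  out
}
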