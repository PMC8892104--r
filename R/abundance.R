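# Gene-catalog relative abundance: the length-normalized abundance
# equation, taxonomic/functional aggregation, and the screening filters
# applied before differential testing.

TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family",
                    "genus", "species")
FUNCTION_SCHEMES <- c("kegg_pathway", "cazy_family", "eggnog_og")

#' Remove genes with insufficient read support
#'
#' Default (`rule = "all"`): a gene is removed iff its mapped read count is
#' below `min_reads` in *every* sample — the permissive reading that
#' matches gene-catalog practice. `rule = "any"` removes a gene when any
#' sample falls below the threshold.
#'
#' @param profile list with `gene_id`, `length`, `counts` (genes x samples).
#' @param min_reads support threshold (default 2 reads).
#' @param rule `"all"` (default) or `"any"`.
#' @return The filtered profile; the number of removed genes is reported
#'   via `message()`.
#' @export
filter_low_support_genes <- function(profile, min_reads = 2,
                                     rule = c("all", "any")) {
  rule <- match.arg(rule)
  if (!length(profile$gene_id)) stop("empty profile")
  low <- profile$counts < min_reads
  drop <- if (rule == "all") rowSums(!low) == 0 else rowSums(low) > 0
  if (all(drop)) {
    stop("all genes removed by the low-support filter (< ", min_reads,
         " reads, rule '", rule, "')")
  }
  message(sum(drop), " of ", length(drop),
          " genes removed by the low-support filter")
  list(gene_id = profile$gene_id[!drop],
       length = profile$length[!drop],
       counts = profile$counts[!drop, , drop = FALSE])
}

#' Gene-level relative abundance
#'
#' Per sample, the abundance of gene k is its length-normalized read count
#' divided by the sample sum of length-normalized counts:
#' `G_k = (r_k / L_k) / sum_i(r_i / L_i)`.
#'
#' @param profile (filtered) gene catalog profile.
#' @return A genes x samples matrix of relative abundances; columns sum to
#'   1 for every sample with mapped reads (all-zero samples yield all-zero
#'   columns with a warning). Carries attribute `level = "gene"`.
#' @export
gene_relative_abundance <- function(profile) {
  if (any(profile$length <= 0)) stop("gene lengths must be positive")
  rate <- profile$counts / profile$length
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("sample(s) with zero mapped reads: ",
            paste(colnames(profile$counts)[tot == 0], collapse = ", "))
  }
  ab <- sweep(rate, 2, ifelse(tot == 0, 1, tot), `/`)
  rownames(ab) <- profile$gene_id
  structure(ab, level = "gene")
}

#' Aggregate gene abundances to a taxonomic rank or functional scheme
#'
#' Feature abundance is the sum of member-gene abundances per sample. At a
#' taxonomic rank each gene contributes to exactly one lineage (genes with
#' no annotation at that rank are collected into an explicit
#' `"unannotated"` row, so per-sample conservation is testable). For a
#' functional scheme a gene annotated to several categories (separated by
#' `;`) contributes its full abundance to each, so functional columns may
#' sum to more than 1.
#'
#' @param gene_abund gene-level abundance matrix.
#' @param annot annotation map with the gene lineages/categories.
#' @param level one of the seven taxonomy ranks or `"kegg_pathway"`,
#'   `"cazy_family"`, `"eggnog_og"`.
#' @return features x samples abundance matrix with attribute `level`.
#' @export
aggregate_by_annotation <- function(gene_abund, annot, level) {
  if (!level %in% c(TAXONOMY_RANKS, FUNCTION_SCHEMES)) {
    stop("unknown level: ", level)
  }
  lab <- annot[[level]][match(rownames(gene_abund), annot$gene_id)]
  if (level %in% TAXONOMY_RANKS) {
    lab[is.na(lab) | lab == ""] <- "unannotated"
    groups <- split(seq_len(nrow(gene_abund)), lab)
  } else {
    keep <- !is.na(lab) & lab != ""
    idx <- rep(seq_len(nrow(gene_abund))[keep],
               lengths(strsplit(lab[keep], ";", fixed = TRUE)))
    cats <- unlist(strsplit(lab[keep], ";", fixed = TRUE))
    groups <- split(idx, cats)
  }
  out <- matrix(0, length(groups), ncol(gene_abund),
                dimnames = list(names(groups), colnames(gene_abund)))
  for (i in seq_along(groups)) {
    out[i, ] <- colSums(gene_abund[groups[[i]], , drop = FALSE])
  }
  structure(out, level = level)
}

#' Prevalence and mean-abundance screen for differential testing
#'
#' A feature passes iff it is present (abundance > 0) in every sample of at
#' least one group AND its within-group mean relative abundance exceeds
#' `min_mean_abund` in at least one group (default 0.1%).
#'
#' @param abund features x samples abundance matrix.
#' @param groups group label per column (two groups, e.g. line).
#' @param min_mean_abund mean relative-abundance threshold (fraction).
#' @return A list with `pass` (feature ids) and `table` (per-feature
#'   presence/mean diagnostics and the reason for failure).
#' @export
prevalence_abundance_filter <- function(abund, groups,
                                        min_mean_abund = 0.001) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) != 2) stop("exactly two groups required")
  if (any(tabulate(factor(groups, gl)) == 0)) stop("group with zero samples")
  g1 <- groups == gl[1]; g2 <- groups == gl[2]
  all1 <- rowSums(abund[, g1, drop = FALSE] > 0) == sum(g1)
  all2 <- rowSums(abund[, g2, drop = FALSE] > 0) == sum(g2)
  m1 <- rowMeans(abund[, g1, drop = FALSE])
  m2 <- rowMeans(abund[, g2, drop = FALSE])
  prevalent <- (all1 | all2) &
    (m1 > min_mean_abund | m2 > min_mean_abund)
  reason <- ifelse(prevalent, "",
                   ifelse(!(all1 | all2), "absent_in_both_groups",
                          "below_mean_abundance"))
  tab <- data.frame(feature = rownames(abund),
                    present_all_1 = all1, present_all_2 = all2,
                    mean_1 = m1, mean_2 = m2, pass = prevalent,
                    reason = reason, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(tab)[2:5] <- c(paste0("present_all_", gl[1]),
                       paste0("present_all_", gl[2]),
                       paste0("mean_", gl[1]), paste0("mean_", gl[2]))
  list(pass = rownames(abund)[prevalent], table = tab)
}
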