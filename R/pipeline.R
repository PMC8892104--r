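# End-to-end orchestration: from a simulated (or loaded) study to the
# per-compartment association report, plus a file-writing pipeline wrapper
# used for reproducibility checks.

#' Size-factor-normalized log2 expression
#'
#' `log2(count / size_factor + 1)`, the default expression scale for the
#' association cascade.
#'
#' @param counts genes x samples matrix.
#' @param sf size factors (default [size_factors()]).
#' @return genes x samples numeric matrix.
#' @export
normalized_expression <- function(counts, sf = size_factors(counts)) {
  log2(sweep(counts, 2, sf, `/`) + 1)
}

#' Run the multi-omics association cascade for one compartment
#'
#' AFRT selection, DE + DEG calling, variance-ranked gene selection,
#' soft-power choice, module construction, AFRT screening of modules,
#' genes and species (the cecal species screen is restricted to
#' Metastats-significant species and uses the stricter p < 0.01 link
#' threshold), and the final species x DEG Spearman correlations.
#'
#' @param sim a `gut_simulation` (or a list with the same elements).
#' @param compartment one of duodenum, jejunum, ileum, ceca.
#' @param n_top_genes genes kept (by variance) for module construction.
#' @param n_perm,seed Metastats permutation settings.
#' @param min_module_size,merge_height,cut_height module parameters.
#' @param powers candidate soft powers.
#' @return A list with the stage outputs: `afrt`, `de`, `modules`,
#'   `gene_screen`, `species_screen`, `differential_species`,
#'   `associations` (with attribute `p_threshold`).
#' @export
run_association_cascade <- function(sim, compartment,
                                    n_top_genes = 750,
                                    n_perm = 5000, seed = 1,
                                    min_module_size = 30,
                                    merge_height = 0.25,
                                    cut_height = "auto",
                                    powers = c(4:10, 12)) {
  design <- sim$design[sim$design$compartment == compartment, ]
  samp <- design$sample_id

  # microbial species abundances, screened to the analysis set
  prof <- filter_low_support_genes(sim$microbiome$profile)
  gab <- gene_relative_abundance(prof)
  species_ab <- aggregate_by_annotation(gab, sim$microbiome$annotation,
                                        "species")
  species_ab <- species_ab[rownames(species_ab) != "unannotated",
                           samp, drop = FALSE]
  filt <- prevalence_abundance_filter(species_ab, design$line)
  species_ab <- species_ab[filt$pass, , drop = FALSE]

  # line-differential species (needed for the cecal restriction); the
  # Monte-Carlo permutation path keeps the per-compartment runtime modest
  ms <- metastats_permutation_test(species_ab, design$line,
                                   n_perm = n_perm,
                                   seed = derive_seed(seed, paste0(
                                     "metastats_", compartment)),
                                   max_exhaustive = 20000)
  diff_species <- ms$feature[ms$q < 0.05]

  # differential expression and DEG calling
  counts <- sim$expression$counts[, samp, drop = FALSE]
  sf <- size_factors(counts)
  de <- call_degs(nb_fit_and_test(counts, design$line, sf))

  # AFRT selection on the birds of this compartment
  phen <- sim$phenotypes[match(design$bird_id, sim$phenotypes$bird_id), ]
  afrt <- select_afrt(phen)
  traits <- as.matrix(phen[, afrt$traits])
  rownames(traits) <- samp

  # co-expression modules on the genes with the most biological (excess
  # over technical) variance; raw variance ranking favours low-count
  # genes whose log-scale measurement noise is large
  expr <- t(normalized_expression(counts, sf))
  vars <- apply(expr, 2, stats::var)
  alpha <- estimate_dispersions(counts, design$line, sf)
  bm <- rowMeans(sweep(counts, 2, sf, `/`))
  tech <- (1 / log(2)^2) * (1 / pmax(bm, 0.5) + alpha)
  score <- vars - tech[colnames(expr)]
  top <- names(sort(score, decreasing = TRUE))[
    seq_len(min(n_top_genes, ncol(expr)))]
  expr_top <- expr[, top, drop = FALSE]
  sp <- pick_soft_power(expr_top, powers = powers)
  modules <- build_modules(expr_top, sp$power,
                           min_module_size = min_module_size,
                           merge_height = merge_height,
                           cut_height = cut_height)
  gene_screen <- screen_genes(modules, expr_top, traits)

  restrict <- if (compartment == "ceca") diff_species else NULL
  species_screen <- screen_microbes(species_ab, traits,
                                    restrict_to = restrict)

  direction <- stats::setNames(ms$direction, ms$feature)
  assoc <- cross_omic_associations(
    species_screen$species, gene_screen$gene_set, de,
    species_ab, expr, compartment, species_direction = direction)

  list(compartment = compartment, afrt = afrt, de = de,
       metastats = ms, differential_species = diff_species,
       soft_power = sp$power, modules = modules,
       gene_screen = gene_screen, species_screen = species_screen,
       associations = assoc)
}

#' Run the full pipeline and write its outputs
#'
#' Simulates a study (or accepts one), then per compartment: diversity,
#' differential taxa, DE results, and the association records; writes
#' deterministic TSV outputs to `out_dir`.
#'
#' @param seed master seed (also used for the simulation when `sim` is
#'   NULL).
#' @param out_dir output directory.
#' @param sim optional pre-built `gut_simulation`.
#' @param ... sizes passed to [simulate_study()] (e.g. `n_host_genes`).
#' @return The per-compartment cascade results, invisibly.
#' @export
run_pipeline <- function(seed, out_dir, sim = NULL, ...) {
  if (is.null(sim)) sim <- simulate_study(seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  prof <- filter_low_support_genes(sim$microbiome$profile)
  gab <- gene_relative_abundance(prof)
  div <- alpha_diversity(gab)
  utils::write.table(format(div, digits = 10),
                     file.path(out_dir, "diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  res <- lapply(GUT_COMPARTMENTS, function(cc) {
    run_association_cascade(sim, cc, seed = seed)
  })
  names(res) <- GUT_COMPARTMENTS

  taxa <- do.call(rbind, lapply(res, function(r) {
    cbind(compartment = r$compartment, r$metastats)
  }))
  utils::write.table(format(taxa, digits = 10),
                     file.path(out_dir, "differential_taxa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  de <- do.call(rbind, lapply(res, function(r) {
    cbind(compartment = r$compartment, r$de)
  }))
  utils::write.table(format(de, digits = 10),
                     file.path(out_dir, "de_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assoc <- do.call(rbind, lapply(res, function(r) r$associations))
  utils::write.table(format(assoc, digits = 10),
                     file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  edges <- if (nrow(assoc)) {
    data.frame(source = assoc$species, target = assoc$gene,
               rho = format(assoc$rho, digits = 10),
               p = format(assoc$p, digits = 10),
               type = "species-gene", stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), target = character(),
               rho = character(), p = character(), type = character())
  }
  utils::write.table(edges, file.path(out_dir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
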