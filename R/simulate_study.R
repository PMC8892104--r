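# Study-level simulation: ties the phenotype, microbiome and expression
# layers together through shared latent factors, with named seed substreams
# per layer so each can be regenerated independently.

#' Default planted scenario
#'
#' The study-shaped default: the full set of planted abdominal-fat relevant
#' serum traits, one adiposity-coupled co-expression module (plus two
#' null modules), one phenotype-coupled species per compartment sharing the
#' module's latent factor, five microbe-gene links per compartment realized
#' through that factor, and line-differential species in the jejunum and
#' ceca. Couplings were fixed a priori from a power analysis at 20 birds.
#'
#' @return A scenario list consumed by [simulate_study()].
#' @export
default_scenario <- function() {
  trait_sp <- data.frame(
    species = c("sp001", "sp002", "sp003", "sp004"),
    compartment = GUT_COMPARTMENTS,
    beta_latent = 2.0, beta_afp = 1.5, latent = "f_mod",
    stringsAsFactors = FALSE
  )
  # the cecal link species is line-differential so it survives the cecal
  # restriction to Metastats-significant species
  differential <- data.frame(
    species = "sp004", log2fc = 2.5, compartment = "ceca",
    stringsAsFactors = FALSE
  )
  link_genes <- list(duodenum = sprintf("hg%04d", 301:305),
                     jejunum = sprintf("hg%04d", 306:310),
                     ileum = sprintf("hg%04d", 311:315),
                     ceca = sprintf("hg%04d", 316:320))
  # link loadings are sign-aligned with the planted line effect (positive
  # log2fc = up in lean = negative loading on the adiposity factor), so
  # the factor coupling reinforces rather than cancels the DEG signal
  lfc <- c(2.5, -2.5, 2.5, -2.5, 2.5)
  links <- do.call(rbind, lapply(GUT_COMPARTMENTS, function(cc) {
    data.frame(gene = link_genes[[cc]],
               species = trait_sp$species[trait_sp$compartment == cc],
               compartment = cc, loading = -sign(lfc) * 0.9,
               latent = "f_mod", stringsAsFactors = FALSE)
  }))
  deg <- do.call(rbind, lapply(GUT_COMPARTMENTS, function(cc) {
    data.frame(gene = link_genes[[cc]], log2fc = lfc,
               compartment = cc, stringsAsFactors = FALSE)
  }))
  # M1 is the adiposity-coupled module; its smaller biological SD keeps the
  # factor-induced line shift of its genes below the DEG threshold
  modules <- list(
    list(name = "M1", genes = sprintf("hg%04d", 1:80), loading = 0.75,
         sd = 0.62, latent = "f_mod", afp_cor = NA),
    list(name = "M2", genes = sprintf("hg%04d", 101:200), loading = 0.8,
         sd = 1.0, latent = NA, afp_cor = 0),
    list(name = "M3", genes = sprintf("hg%04d", 201:300), loading = 0.8,
         sd = 1.0, latent = NA, afp_cor = 0)
  )
  list(
    phenotype_params = phenotype_params(),
    latent_afp_cor = 0.7,
    microbiome = list(differential = differential,
                      trait_correlated = trait_sp),
    expression = list(deg = deg, modules = modules, links = links)
  )
}

#' Scenario mimicking the study's reported structure
#'
#' Plants two jejunal and four cecal line-differential species and
#' phenotype-coupled species counts of 2/7/3/4 across duodenum, jejunum,
#' ileum and ceca (the cecal four are also the differential four, since the
#' cecal association screen is restricted to line-differential species).
#' Keeps the default module/link/DEG layer so the association report is
#' populated in every compartment.
#'
#' @return A scenario list consumed by [simulate_study()].
#' @export
structural_scenario <- function() {
  sc <- default_scenario()
  trait_sp <- data.frame(
    species = c("sp001", "sp010",
                "sp002", sprintf("sp%03d", 11:16),
                "sp003", "sp021", "sp022",
                "sp004", "sp031", "sp032", "sp033"),
    compartment = c(rep("duodenum", 2), rep("jejunum", 7),
                    rep("ileum", 3), rep("ceca", 4)),
    beta_latent = 0, beta_afp = 2.5, latent = NA_character_,
    stringsAsFactors = FALSE
  )
  # the link species keep the shared-latent coupling so links still exist
  anchor <- trait_sp$species %in% c("sp001", "sp002", "sp003", "sp004")
  trait_sp$beta_latent[anchor] <- 2.0
  trait_sp$beta_afp[anchor] <- 1.5
  trait_sp$latent[anchor] <- "f_mod"
  differential <- data.frame(
    species = c("sp015", "sp016", "sp004", "sp031", "sp032", "sp033"),
    log2fc = c(3, -3, 2.5, -2.5, 3, -3),
    compartment = c("jejunum", "jejunum", rep("ceca", 4)),
    stringsAsFactors = FALSE
  )
  sc$microbiome <- list(differential = differential,
                        trait_correlated = trait_sp)
  sc
}

#' Simulate a complete two-line, four-compartment study
#'
#' Generates phenotypes, gene-catalog microbiome and expression data with
#' recorded ground truth. All randomness flows from `seed` through named
#' substreams (`phenotypes`, `latents`, `microbiome`, `expression`).
#'
#' @param seed master integer seed.
#' @param n_per_line birds per line.
#' @param n_species,n_genes_per_species,n_host_genes problem sizes.
#' @param depth mean metagenome sequencing depth per sample.
#' @param scenario planted-effect scenario, e.g. [default_scenario()].
#' @return A list of class `gut_simulation` with elements `phenotypes`,
#'   `design`, `microbiome`, `expression` and `truth` (consolidated planted
#'   ground truth including the planted microbe-gene links).
#' @export
simulate_study <- function(seed = 1, n_per_line = 10, n_species = 300,
                           n_genes_per_species = 20, n_host_genes = 5000,
                           depth = 1e5, scenario = default_scenario()) {
  phen <- generate_phenotypes(n_per_line, scenario$phenotype_params,
                              seed = derive_seed(seed, "phenotypes"))
  afp_z <- afp_zscore(phen$phenotypes)
  lat_seed <- derive_seed(seed, "latents")
  latents <- with_seed(lat_seed, {
    ac <- scenario$latent_afp_cor
    grid <- expand.grid(bird_id = phen$phenotypes$bird_id,
                        compartment = GUT_COMPARTMENTS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$value <- ac * afp_z[grid$bird_id] +
      sqrt(1 - ac^2) * stats::rnorm(nrow(grid))
    list(f_mod = grid)
  })
  micro <- generate_microbiome(phen$design, phen$phenotypes,
                               n_species = n_species,
                               n_genes_per_species = n_genes_per_species,
                               truth_spec = scenario$microbiome,
                               latents = latents, depth = depth,
                               seed = derive_seed(seed, "microbiome"))
  expr <- generate_expression(phen$design, phen$phenotypes,
                              n_genes = n_host_genes,
                              truth_spec = scenario$expression,
                              latents = latents,
                              seed = derive_seed(seed, "expression"))
  links <- scenario$expression$links
  truth <- list(
    afrt_traits = c(phen$truth$trait_correlated$trait, "HDL_C_LDL_C"),
    differential_species = scenario$microbiome$differential,
    trait_correlated_species = scenario$microbiome$trait_correlated,
    true_deg = scenario$expression$deg,
    module_membership = expr$truth$module_membership,
    trait_coupled_module = "M1",
    planted_links = links[, c("compartment", "species", "gene")],
    seed = seed
  )
  structure(list(phenotypes = phen$phenotypes, design = phen$design,
                 latent = phen$latent, microbiome = micro,
                 expression = expr, truth = truth),
            class = "gut_simulation")
}

#' @export
print.gut_simulation <- function(x, ...) {
  cat("Synthetic two-line gut study (seed ", x$truth$seed, ")\n", sep = "")
  cat("  birds: ", nrow(x$phenotypes), " (",
      sum(x$phenotypes$line == "lean"), " lean / ",
      sum(x$phenotypes$line == "fat"), " fat)\n", sep = "")
  cat("  samples: ", nrow(x$design), " across ",
      length(unique(x$design$compartment)), " compartments\n", sep = "")
  cat("  catalog genes: ", length(x$microbiome$profile$gene_id),
      " (", nrow(x$microbiome$truth$species_proportions), " species)\n",
      sep = "")
  cat("  host genes: ", nrow(x$expression$counts), "\n", sep = "")
  cat("  planted: ", nrow(x$truth$differential_species),
      " differential species, ",
      nrow(x$truth$true_deg), " DEGs, ",
      nrow(x$truth$planted_links), " microbe-gene links\n", sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the tab-separated matrices and metadata the analysis stages read:
#' `gene_counts.tsv` (gene_id, length, one column per sample),
#' `annotation.tsv`, `expr_counts.tsv`, `phenotypes.csv`, `design.tsv`,
#' `pathway_map.tsv` and `truth.json`.
#'
#' @param sim a `gut_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gc <- data.frame(gene_id = sim$microbiome$profile$gene_id,
                   length = sim$microbiome$profile$length,
                   sim$microbiome$profile$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gc, file.path(dir, "gene_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$microbiome$annotation,
                     file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  ec <- data.frame(gene_id = rownames(sim$expression$counts),
                   sim$expression$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(ec, file.path(dir, "expr_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expression$pathway_map,
                     file.path(dir, "pathway_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$module_membership <- as.list(truth$module_membership[
    !is.na(truth$module_membership)])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  invisible(dir)
}

#' Read study matrices written by [write_simulation()]
#'
#' The same dialect is accepted for real data exported from upstream
#' quantification: tab-separated, one header line, samples in columns.
#'
#' @param dir directory containing the files.
#' @return A list with `profile`, `annotation`, `expr_counts`,
#'   `phenotypes`, `design`, `pathway_map`.
#' @export
read_study <- function(dir) {
  gc <- utils::read.table(file.path(dir, "gene_counts.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(gc[, -(1:2), drop = FALSE])
  rownames(counts) <- gc$gene_id
  storage.mode(counts) <- "integer"
  ec <- utils::read.table(file.path(dir, "expr_counts.tsv"), sep = "\t",
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  expr <- as.matrix(ec[, -1, drop = FALSE])
  rownames(expr) <- ec$gene_id
  storage.mode(expr) <- "integer"
  list(
    profile = list(gene_id = gc$gene_id, length = gc$length,
                   counts = counts),
    annotation = utils::read.table(file.path(dir, "annotation.tsv"),
                                   sep = "\t", header = TRUE,
                                   na.strings = "",
                                   stringsAsFactors = FALSE),
    expr_counts = expr,
    phenotypes = utils::read.csv(file.path(dir, "phenotypes.csv"),
                                 stringsAsFactors = FALSE),
    design = utils::read.table(file.path(dir, "design.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE),
    pathway_map = utils::read.table(file.path(dir, "pathway_map.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  )
}
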