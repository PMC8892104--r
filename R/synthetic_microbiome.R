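# Synthetic gut-metagenome generator.
#
# Species baseline abundances are log-normal, perturbed per line/compartment
# (planted differential species) and per bird (planted phenotype-coupled
# species), renormalized to proportions, and converted to gene-level mapped
# read counts by multinomial sampling with length-proportional weights.
# Because every species carries the same number of catalog genes, the
# length normalization in the abundance equation exactly undoes the
# length-proportional read sampling, so summing gene-level relative
# abundances per species recovers the species proportions in expectation.

#' Generate a synthetic gene-catalog profile with planted effects
#'
#' @param design sample design (one row per bird-compartment sample).
#' @param phenotypes phenotype table from [generate_phenotypes()]; required
#'   when `truth_spec` plants phenotype-coupled species.
#' @param n_species number of microbial species (>= 2).
#' @param n_genes_per_species catalog genes per species.
#' @param truth_spec list with optional elements:
#'   * `differential`: data.frame(`species`, `log2fc`, `compartment`);
#'     positive `log2fc` = more abundant in the fat line; `compartment`
#'     may be `"all"`.
#'   * `trait_correlated`: data.frame(`species`, `compartment`,
#'     `beta_latent`, `beta_afp`, `latent`); log abundance gains
#'     `noise_sd * (beta_latent * latent + beta_afp * afp_z)` for the
#'     bird, where `latent` names an entry of `latents` (NA = none) and
#'     `afp_z` is the standardized abdominal-fat percentage.
#' @param latents named list of data.frames(`bird_id`, `compartment`,
#'   `value`): shared latent factors (also used by the expression layer to
#'   realize planted microbe-gene links).
#' @param depth mean sequencing depth (mapped reads per sample).
#' @param seed integer seed.
#' @param base_sd SD of species log-baselines (default 2: gut
#'   communities are heavy-tailed - a few dominant species plus a long
#'   rare tail - but a too-extreme tail makes one species's noise a
#'   global compositional factor for the whole community).
#' @param comp_sd SD of species-by-compartment baseline shifts.
#' @param noise_sd per-sample log-abundance noise SD (the scale against
#'   which planted couplings are expressed).
#' @param si_present_frac fraction of species present in the small
#'   intestine (drawn once per species; default 0.18). Cecal communities
#'   are far richer than small-intestinal ones - the study reports a far
#'   greater number of cecal species, and most catalog genes were
#'   identified in the ceca. Planted species are always present in their
#'   target compartments.
#' @param frac_unannotated fraction of genes left without taxonomy, to
#'   emulate catalog genes that fail annotation.
#' @return A list with `profile` (gene_id, length, counts matrix),
#'   `annotation` (gene-level 7-rank lineage + functional categories),
#'   and `truth` (true species proportions, planted effects, latents, seed).
#' @export
generate_microbiome <- function(design, phenotypes = NULL, n_species = 300,
                                n_genes_per_species = 20,
                                truth_spec = list(), latents = NULL,
                                depth = 1e5, seed = 1, base_sd = 2,
                                comp_sd = 0.75, noise_sd = 0.5,
                                si_present_frac = 0.18,
                                frac_unannotated = 0.03) {
  check_design(design)
  if (n_species < 2) stop("need at least 2 species")
  species <- sprintf("sp%03d", seq_len(n_species))
  diff_spec <- truth_spec$differential
  trait_spec <- truth_spec$trait_correlated
  planted <- unique(c(diff_spec$species, trait_spec$species))
  if (length(bad <- setdiff(planted, species))) {
    stop("planted species not in catalog: ", paste(bad, collapse = ", "))
  }
  afp_z <- NULL
  if (!is.null(trait_spec) && nrow(trait_spec)) {
    if (is.null(phenotypes)) stop("phenotypes required for planted couplings")
    afp_z <- afp_zscore(phenotypes)
  }

  with_seed(seed, {
    mu <- stats::rnorm(n_species, 0, base_sd)
    names(mu) <- species
    # planted species sit at a moderate fixed baseline: abundant enough
    # to quantify reliably and to pass the 0.1% screen, but low enough
    # that even their largest planted swings stay in the percent range -
    # a dominant planted species would drag every other proportion
    # through renormalization and smear its coupling over the community
    mu[planted] <- 0.65 * base_sd
    shift <- matrix(stats::rnorm(n_species * 4, 0, comp_sd), n_species, 4,
                    dimnames = list(species, GUT_COMPARTMENTS))
    # sparse small-intestinal communities: most species are ceca-only
    si_present <- stats::runif(n_species) < si_present_frac
    names(si_present) <- species
    planted_comps <- lapply(stats::setNames(nm = species),
                            function(s) character(0))
    for (df in list(diff_spec, trait_spec)) {
      if (!is.null(df) && nrow(df)) {
        for (i in seq_len(nrow(df))) {
          comps <- if (df$compartment[i] == "all") GUT_COMPARTMENTS else
            strsplit(df$compartment[i], ",")[[1]]
          planted_comps[[df$species[i]]] <-
            union(planted_comps[[df$species[i]]], comps)
        }
      }
    }

    n_samp <- nrow(design)
    logA <- matrix(0, n_species, n_samp, dimnames = list(species,
                                                         design$sample_id))
    for (j in seq_len(n_samp)) {
      cc <- design$compartment[j]
      v <- mu + shift[, cc]
      if (cc != "ceca") {
        absent <- !si_present &
          !vapply(planted_comps, function(pc) cc %in% pc, logical(1))
        v[absent] <- v[absent] - 10
        # keep planted species at the same *relative* abundance in the
        # smaller small-intestinal community
        v[planted] <- v[planted] + log(si_present_frac)
      }
      logA[, j] <- v
    }
    if (!is.null(diff_spec) && nrow(diff_spec)) {
      if (any(!is.finite(diff_spec$log2fc))) stop("planted log2fc non-finite")
      for (i in seq_len(nrow(diff_spec))) {
        comps <- if (diff_spec$compartment[i] == "all") GUT_COMPARTMENTS else
          strsplit(diff_spec$compartment[i], ",")[[1]]
        sel <- design$line == "fat" & design$compartment %in% comps
        logA[diff_spec$species[i], sel] <-
          logA[diff_spec$species[i], sel] + log(2) * diff_spec$log2fc[i]
      }
    }
    if (!is.null(trait_spec) && nrow(trait_spec)) {
      for (i in seq_len(nrow(trait_spec))) {
        comps <- if (trait_spec$compartment[i] == "all") GUT_COMPARTMENTS else
          strsplit(trait_spec$compartment[i], ",")[[1]]
        sel <- which(design$compartment %in% comps)
        lat <- rep(0, length(sel))
        lname <- trait_spec$latent[i]
        if (!is.na(lname) && nzchar(lname)) {
          ldf <- latents[[lname]]
          if (is.null(ldf)) stop("unknown latent: ", lname)
          key <- paste(ldf$bird_id, ldf$compartment)
          lat <- ldf$value[match(paste(design$bird_id[sel],
                                       design$compartment[sel]), key)]
        }
        bump <- noise_sd * (trait_spec$beta_latent[i] * lat +
                              trait_spec$beta_afp[i] *
                                afp_z[design$bird_id[sel]])
        logA[trait_spec$species[i], sel] <-
          logA[trait_spec$species[i], sel] + bump
      }
    }
    # abundance-dependent stability: dominant taxa fluctuate less on the
    # log scale than rare ones (and a noisy dominant species would act as
    # a spurious compositional factor for the whole community)
    stab <- 0.5 + 0.5 / (1 + exp(mu - stats::qnorm(0.85) * base_sd))
    logA <- logA + matrix(stats::rnorm(length(logA), 0, noise_sd),
                          nrow(logA)) * stab
    p_species <- apply(exp(logA), 2, function(x) x / sum(x))

    # gene catalog: lengths log-normal around the study's mean ORF size
    n_genes <- n_species * n_genes_per_species
    gene_id <- sprintf("mg%05d", seq_len(n_genes))
    gene_species <- rep(species, each = n_genes_per_species)
    len <- pmax(100L, as.integer(round(stats::rlnorm(n_genes, log(500), 0.4))))

    depth_j <- as.integer(round(depth * exp(stats::rnorm(n_samp, 0, 0.2))))
    counts <- matrix(0L, n_genes, n_samp,
                     dimnames = list(gene_id, design$sample_id))
    for (j in seq_len(n_samp)) {
      w <- p_species[gene_species, j] * len
      counts[, j] <- stats::rmultinom(1, depth_j[j], w)[, 1]
    }

    annotation <- build_annotation(gene_id, gene_species, species,
                                   frac_unannotated)
    truth <- list(species_proportions = p_species,
                  differential = diff_spec, trait_correlated = trait_spec,
                  latents = latents, depths = depth_j, seed = seed)
    list(profile = list(gene_id = gene_id, length = len, counts = counts),
         annotation = annotation, truth = truth)
  })
}

# Build a prefix-consistent 7-rank lineage per species plus functional
# categories per gene. Firmicutes and Bacteroidetes are always represented
# so the F/B ratio is defined.
build_annotation <- function(gene_id, gene_species, species,
                             frac_unannotated) {
  n_species <- length(species)
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Tenericutes", "Verrucomicrobia")
  probs <- c(0.60, 0.20, 0.10, 0.05, 0.03, 0.02)
  sp_phylum <- sample(phyla, n_species, replace = TRUE, prob = probs)
  sp_phylum[1:2] <- c("Firmicutes", "Bacteroidetes")
  genus_idx <- integer(n_species)
  for (ph in phyla) {
    i <- which(sp_phylum == ph)
    genus_idx[i] <- ceiling(seq_along(i) / 3)
  }
  lineage <- data.frame(
    species_id = species,
    kingdom = "Bacteria",
    phylum = sp_phylum,
    class = paste0(sp_phylum, "_class"),
    order = paste0(sp_phylum, "_order"),
    family = paste0(sp_phylum, "_family"),
    genus = paste0(tolower(substr(sp_phylum, 1, 4)), "_g", genus_idx),
    stringsAsFactors = FALSE
  )
  lineage$species <- species

  idx <- match(gene_species, species)
  ann <- data.frame(gene_id = gene_id, stringsAsFactors = FALSE)
  for (rk in c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")) {
    ann[[rk]] <- lineage[[rk]][idx]
  }
  drop <- stats::runif(length(gene_id)) < frac_unannotated
  ann[drop, c("kingdom", "phylum", "class", "order", "family", "genus",
              "species")] <- NA

  kegg <- sprintf("map%05d", sample(30, length(gene_id), replace = TRUE))
  two <- stats::runif(length(gene_id)) < 0.10
  kegg[two] <- paste(kegg[two],
                     sprintf("map%05d", sample(30, sum(two), replace = TRUE)),
                     sep = ";")
  kegg[stats::runif(length(gene_id)) < 0.15] <- NA
  cazy <- ifelse(stats::runif(length(gene_id)) < 0.20,
                 sprintf("GH%d", sample(40, length(gene_id), replace = TRUE)),
                 NA)
  eggnog <- ifelse(stats::runif(length(gene_id)) < 0.70,
                   sprintf("COG%04d",
                           sample(30, length(gene_id), replace = TRUE)),
                   NA)
  ann$kegg_pathway <- kegg
  ann$cazy_family <- cazy
  ann$eggnog_og <- eggnog
  ann
}
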