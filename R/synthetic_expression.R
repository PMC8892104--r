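# Synthetic intestinal RNA-seq generator.
#
# Counts are negative-binomial with per-sample depth factors and per-gene
# dispersions. Planted structure on the log2 scale: line effects for DEGs
# (positive log2fc = higher in the lean line), latent-factor driven
# co-expression modules (optionally coupled to the adiposity phenotype),
# and microbe-gene links realized by loading a gene on the same latent
# factor that perturbs a planted species in the microbiome layer.

#' Generate synthetic expression counts with planted effects
#'
#' @param design sample design (one row per bird-compartment sample).
#' @param phenotypes phenotype table; required when modules are coupled to
#'   the adiposity phenotype.
#' @param n_genes number of host genes.
#' @param truth_spec list with optional elements:
#'   * `deg`: data.frame(`gene`, `log2fc`, `compartment`); positive
#'     `log2fc` = higher in lean (lean vs fat); `compartment` may be "all".
#'   * `modules`: list of `list(name, genes, loading, latent, afp_cor)`
#'     (optional `sd` overrides `module_sd` for that module).
#'     `genes` is a character vector of gene ids (>= 3); module genes get
#'     `loading * module_sd * f + sqrt(1 - loading^2) * module_sd * e`,
#'     where the per-compartment factor `f` is looked up in `latents` by
#'     `latent`, or built as `afp_cor * afp_z + sqrt(1 - afp_cor^2) * eta`
#'     when `latent` is `NA`.
#'   * `links`: data.frame(`gene`, `species`, `compartment`, `loading`,
#'     `latent`); the gene loads on the named shared latent in that
#'     compartment, realizing the planted microbe-gene association.
#' @param latents named list of data.frames(`bird_id`, `compartment`,
#'   `value`), shared with [generate_microbiome()].
#' @param seed integer seed.
#' @param depth_sd SD of log per-sample depth factors (geometric mean 1).
#' @param base_mean_log2,base_sd_log2 log2-scale baseline mean/SD for
#'   unplanted genes; planted genes draw baselines from N(6, 1) so they sit
#'   at reliably quantifiable expression.
#' @param bio_sd log2 biological SD of unplanted genes (default 0.35;
#'   most genes are biologically stable).
#' @param module_sd log2 marginal biological SD of module and link genes.
#' @param dispersion_meanlog,dispersion_sdlog log-normal NB dispersion
#'   parameters.
#' @return A list with `counts` (genes x samples integer matrix),
#'   `pathway_map` (gene_id, pathway_id, pathway_name) and `truth`
#'   (planted DEGs, module membership, links, module factors, depth
#'   factors, dispersions, seed).
#' @export
generate_expression <- function(design, phenotypes = NULL, n_genes = 5000,
                                truth_spec = list(), latents = NULL,
                                seed = 1, depth_sd = 0.25,
                                base_mean_log2 = 5, base_sd_log2 = 2,
                                bio_sd = 0.35, module_sd = 1.2,
                                dispersion_meanlog = log(0.05),
                                dispersion_sdlog = 0.3) {
  check_design(design)
  genes <- sprintf("hg%04d", seq_len(n_genes))
  deg <- truth_spec$deg
  modules <- truth_spec$modules
  links <- truth_spec$links
  if (!is.null(deg) && nrow(deg)) {
    if (any(!is.finite(deg$log2fc))) stop("planted log2fc non-finite")
    if (length(bad <- setdiff(deg$gene, genes))) {
      stop("planted DEG not in gene set: ", paste(bad, collapse = ", "))
    }
  }
  for (m in modules) {
    if (length(m$genes) < 3) stop("module size < 3: ", m$name)
  }
  needs_afp <- any(vapply(modules, function(m) {
    is.null(m$latent) || is.na(m$latent)
  }, logical(1)))
  afp_z <- NULL
  if (!is.null(phenotypes)) afp_z <- afp_zscore(phenotypes)
  if (needs_afp && length(modules) &&
      any(vapply(modules, function(m) isTRUE(m$afp_cor != 0), logical(1))) &&
      is.null(afp_z)) {
    stop("phenotypes required for adiposity-coupled modules")
  }

  with_seed(seed, {
    planted_genes <- unique(c(deg$gene, links$gene,
                              unlist(lapply(modules, `[[`, "genes"))))
    b <- stats::rnorm(n_genes, base_mean_log2, base_sd_log2)
    names(b) <- genes
    b[planted_genes] <- stats::rnorm(length(planted_genes), 6, 1)
    alpha <- stats::rlnorm(n_genes, dispersion_meanlog, dispersion_sdlog)
    names(alpha) <- genes

    n_samp <- nrow(design)
    depth_f <- exp(stats::rnorm(n_samp, 0, depth_sd))
    depth_f <- depth_f / exp(mean(log(depth_f)))
    names(depth_f) <- design$sample_id

    # per-sample log2 signal matrix
    x <- matrix(0, n_genes, n_samp, dimnames = list(genes, design$sample_id))
    lean <- design$line == "lean"
    if (!is.null(deg) && nrow(deg)) {
      for (i in seq_len(nrow(deg))) {
        comps <- if (deg$compartment[i] == "all") GUT_COMPARTMENTS else
          strsplit(deg$compartment[i], ",")[[1]]
        in_comp <- design$compartment %in% comps
        x[deg$gene[i], in_comp & lean] <-
          x[deg$gene[i], in_comp & lean] + deg$log2fc[i] / 2
        x[deg$gene[i], in_comp & !lean] <-
          x[deg$gene[i], in_comp & !lean] - deg$log2fc[i] / 2
      }
    }

    lookup_latent <- function(lname) {
      ldf <- latents[[lname]]
      if (is.null(ldf)) stop("unknown latent: ", lname)
      key <- paste(ldf$bird_id, ldf$compartment)
      ldf$value[match(paste(design$bird_id, design$compartment), key)]
    }

    module_map <- stats::setNames(rep(NA_character_, n_genes), genes)
    factors <- list()
    special_sd <- unique(c(links$gene,
                           unlist(lapply(modules, `[[`, "genes"))))
    for (m in modules) {
      if (!is.null(m$latent) && !is.na(m$latent)) {
        f <- lookup_latent(m$latent)
      } else {
        eta <- stats::rnorm(nlevels(factor(design$bird_id)) * 4)
        key <- paste(design$bird_id, design$compartment)
        eta <- stats::setNames(stats::rnorm(length(unique(key))), unique(key))
        ac <- if (is.null(m$afp_cor)) 0 else m$afp_cor
        base <- if (ac != 0) afp_z[design$bird_id] else 0
        f <- ac * base + sqrt(1 - ac^2) * eta[key]
      }
      factors[[m$name]] <- f
      lg <- m$genes
      module_map[lg] <- m$name
      msd <- if (is.null(m$sd)) module_sd else m$sd
      e <- matrix(stats::rnorm(length(lg) * n_samp), length(lg), n_samp)
      x[lg, ] <- x[lg, ] + m$loading * msd * rep(f, each = length(lg)) +
        sqrt(1 - m$loading^2) * msd * e
    }
    if (!is.null(links) && nrow(links)) {
      for (i in seq_len(nrow(links))) {
        f <- lookup_latent(links$latent[i])
        in_comp <- design$compartment %in%
          (if (links$compartment[i] == "all") GUT_COMPARTMENTS else
             strsplit(links$compartment[i], ",")[[1]])
        g <- links$gene[i]
        x[g, in_comp] <- x[g, in_comp] +
          links$loading[i] * module_sd * f[in_comp]
        x[g, !in_comp] <- x[g, !in_comp] +
          stats::rnorm(sum(!in_comp), 0, module_sd)
      }
    }
    # residual biological noise for genes not already given a module-scale
    # residual above
    plain <- setdiff(genes, special_sd)
    x[plain, ] <- x[plain, ] +
      matrix(stats::rnorm(length(plain) * n_samp, 0, bio_sd),
             length(plain), n_samp)
    link_only <- setdiff(links$gene, unlist(lapply(modules, `[[`, "genes")))
    if (length(link_only)) {
      for (g in link_only) {
        ld <- links$loading[match(g, links$gene)]
        x[g, ] <- x[g, ] + stats::rnorm(n_samp, 0,
                                        sqrt(1 - ld^2) * module_sd)
      }
    }

    mu <- 2^(b + x) * rep(depth_f, each = n_genes)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = rep(1 / alpha, n_samp)),
      n_genes, n_samp, dimnames = list(genes, design$sample_id)
    )
    storage.mode(counts) <- "integer"

    pathway_map <- make_pathway_map(genes, deg)
    truth <- list(deg = deg, module_membership = module_map, links = links,
                  module_factors = factors, depth_factors = depth_f,
                  dispersions = alpha, latents = latents,
                  enriched_pathways = attr(pathway_map, "enriched"),
                  seed = seed)
    list(counts = counts, pathway_map = pathway_map, truth = truth)
  })
}

# Assign genes to named pathways, concentrating a planted fraction of DEGs
# into two pathways so the enrichment stage has true positives.
make_pathway_map <- function(genes, deg) {
  n_path <- 25
  path_id <- sprintf("pw%02d", seq_len(n_path))
  assign <- sample(path_id, length(genes), replace = TRUE)
  names(assign) <- genes
  enriched <- character(0)
  if (!is.null(deg) && nrow(deg)) {
    dg <- unique(deg$gene)
    enriched <- c("pw01", "pw02")
    take <- dg[stats::runif(length(dg)) < 0.6]
    assign[take] <- sample(enriched, length(take), replace = TRUE)
  }
  map <- data.frame(gene_id = genes, pathway_id = assign,
                    pathway_name = paste0("pathway_",
                                          sub("pw", "", assign)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(map, "enriched") <- enriched
  map
}
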