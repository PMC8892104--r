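# Generator tests: study-shaped phenotypes, planted-effect recovery
# surfaces, reproducibility and self-consistency.

test_that("phenotype generator reproduces line means and the AFP identity", {
  out <- generate_phenotypes(n_per_line = 10, seed = 1)
  ph <- out$phenotypes
  pp <- phenotype_params()
  # line means within 3 standard errors of the configured values
  for (tr in c("AFW", "BW", "GLU", "TP")) {
    se_l <- pp$lean_sd[pp$trait == tr] / sqrt(10)
    se_f <- pp$fat_sd[pp$trait == tr] / sqrt(10)
    expect_lt(abs(mean(ph[[tr]][ph$line == "lean"]) -
                    pp$lean_mean[pp$trait == tr]), 3 * se_l)
    expect_lt(abs(mean(ph[[tr]][ph$line == "fat"]) -
                    pp$fat_mean[pp$trait == tr]), 3 * se_f)
  }
  expect_true(all(ph$AFW >= 0))
  expect_equal(ph$AFP, 100 * ph$AFW / (1000 * ph$BW))
  expect_equal(ph$HDL_C_LDL_C, ph$HDL_C / ph$LDL_C)
  # design invariants: each bird once per compartment, unique sample ids
  d <- out$design
  expect_false(anyDuplicated(d$sample_id) > 0)
  expect_true(all(table(d$bird_id, d$compartment) == 1))
  expect_setequal(unique(d$line), c("lean", "fat"))
})

test_that("zero line effects give a calibrated null for the AFW t-test", {
  pp <- phenotype_params()
  pp$fat_mean <- pp$lean_mean
  pp$fat_sd <- pp$lean_sd
  pv <- vapply(1:60, function(s) {
    ph <- generate_phenotypes(10, pp, seed = s)$phenotypes
    line_t_test(ph$AFW[ph$line == "lean"], ph$AFW[ph$line == "fat"])$p
  }, numeric(1))
  expect_gt(mean(pv < 0.05), 0)         # not degenerate
  expect_lt(mean(pv < 0.05), 0.15)      # near the nominal rate
  expect_gt(mean(pv), 0.35)             # roughly uniform
  expect_lt(mean(pv), 0.65)
})

test_that("a planted AFP-GLU correlation of -0.8 is realized in samples", {
  ph <- generate_phenotypes(n_per_line = 50, seed = 3)$phenotypes
  r <- cor(ph$AFP, ph$GLU)
  expect_gt(r, -0.95)
  expect_lt(r, -0.6)
})

test_that("generator rejects invalid parameterizations", {
  pp <- phenotype_params()
  pp$lean_sd[3] <- -1
  expect_error(generate_phenotypes(10, pp, seed = 1), "positive")
  pp <- phenotype_params()
  pp$afp_cor[3] <- 1.5
  expect_error(generate_phenotypes(10, pp, seed = 1), "\\[-1, 1\\]")
  expect_error(generate_phenotypes(2, seed = 1))
})

test_that("a non-PSD requested correlation matrix falls back to nearest PD", {
  pp <- phenotype_params()
  nt <- nrow(pp)
  cm <- diag(nt)
  cm[1, 2] <- cm[2, 1] <- 0.9
  cm[1, 3] <- cm[3, 1] <- 0.9
  cm[2, 3] <- cm[3, 2] <- -0.9   # impossible triangle
  attr(pp, "cor_matrix") <- cm
  expect_message(generate_phenotypes(10, pp, seed = 1),
                 "nearest valid correlation")
})

test_that("two equal species are recovered at 0.5/0.5 through the profile", {
  design <- make_two_group_design(3)
  mic <- generate_microbiome(design, n_species = 2, n_genes_per_species = 10,
                             depth = 5e5, seed = 4, base_sd = 0,
                             comp_sd = 0, noise_sd = 0,
                             si_present_frac = 1, frac_unannotated = 0)
  ab <- gene_relative_abundance(mic$profile)
  sp <- aggregate_by_annotation(ab, mic$annotation, "species")
  expect_true(all(abs(sp - 0.5) < 0.02))
})

test_that("planted cecal differential species are flagged by the pipeline", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    design <- make_two_group_design(10)
    ts <- list(differential = data.frame(species = "sp010", log2fc = 3,
                                         compartment = "ceca"))
    mic <- generate_microbiome(design, n_species = 80,
                               n_genes_per_species = 5, truth_spec = ts,
                               depth = 3e4, seed = s)
    prof <- suppressMessages(filter_low_support_genes(mic$profile))
    ab <- gene_relative_abundance(prof)
    sp <- aggregate_by_annotation(ab, mic$annotation, "species")
    dc <- design[design$compartment == "ceca", ]
    sp <- sp[rownames(sp) != "unannotated", dc$sample_id]
    filt <- prevalence_abundance_filter(sp, dc$line)
    ms <- metastats_permutation_test(sp[filt$pass, , drop = FALSE],
                                     dc$line, n_perm = 2000, seed = s,
                                     max_exhaustive = 1000)
    hits <- hits + (("sp010" %in% ms$feature) &&
                      ms$q[ms$feature == "sp010"] < 0.05)
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("an empty truth spec yields chance-level differential calls", {
  design <- make_two_group_design(10)
  mic <- generate_microbiome(design, n_species = 150,
                             n_genes_per_species = 5, depth = 5e4, seed = 8)
  ab <- gene_relative_abundance(
    suppressMessages(filter_low_support_genes(mic$profile)))
  sp <- aggregate_by_annotation(ab, mic$annotation, "species")
  dc <- design[design$compartment == "ceca", ]
  sp <- sp[rownames(sp) != "unannotated", dc$sample_id]
  filt <- prevalence_abundance_filter(sp, dc$line)
  ms <- metastats_permutation_test(sp[filt$pass, , drop = FALSE], dc$line,
                                   n_perm = 1000, seed = 8,
                                   max_exhaustive = 1000)
  expect_gt(mean(ms$p < 0.05), 0.005)
  expect_lt(mean(ms$p < 0.05), 0.12)
})

test_that("expression counts approach the Poisson limit at zero dispersion", {
  design <- make_two_group_design(10)
  ex <- generate_expression(design, n_genes = 1000, seed = 5,
                            depth_sd = 0, bio_sd = 0,
                            dispersion_meanlog = log(1e-8),
                            dispersion_sdlog = 0)
  cnt <- ex$counts[, design$sample_id[design$compartment == "duodenum"]]
  m <- rowMeans(cnt)
  v <- apply(cnt, 1, var)
  keep <- m > 20
  expect_equal(mean(v[keep] / m[keep]), 1, tolerance = 0.05)
})

test_that("identical seeds and configs give byte-identical simulations", {
  a <- simulate_study(seed = 7, n_species = 40, n_genes_per_species = 4,
                      n_host_genes = 400, depth = 1e4)
  b <- simulate_study(seed = 7, n_species = 40, n_genes_per_species = 4,
                      n_host_genes = 400, depth = 1e4)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$microbiome$profile$counts, b$microbiome$profile$counts)
  expect_identical(a$expression$counts, b$expression$counts)
  c <- simulate_study(seed = 8, n_species = 40, n_genes_per_species = 4,
                      n_host_genes = 400, depth = 1e4)
  expect_false(identical(a$expression$counts, c$expression$counts))
})

test_that("every planted effect appears exactly once in the truth record", {
  sim <- simulate_study(seed = 2, n_species = 60, n_genes_per_species = 4,
                        n_host_genes = 500)
  tr <- sim$truth
  expect_false(anyDuplicated(paste(tr$differential_species$species,
                                   tr$differential_species$compartment)) > 0)
  expect_false(anyDuplicated(paste(tr$planted_links$species,
                                   tr$planted_links$gene,
                                   tr$planted_links$compartment)) > 0)
  # planted links connect trait-correlated species to true DEGs
  expect_true(all(tr$planted_links$species %in%
                    tr$trait_correlated_species$species))
  expect_true(all(tr$planted_links$gene %in% tr$true_deg$gene))
  # module membership covers the configured modules
  expect_setequal(setdiff(unique(tr$module_membership), NA),
                  c("M1", "M2", "M3"))
})
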