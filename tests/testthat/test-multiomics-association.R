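# Correlation utilities, AFRT selection, module construction and the
# cross-omic association cascade.

test_that("correlations match closed forms and the cor.test oracle", {
  x <- c(1, 2, 3, 4, 5)
  out <- correlation_with_p(x, 2 * x + 3, "pearson")
  expect_equal(out$r, 1)
  expect_equal(out$p, 0)
  # monotone transform: Spearman sees the ranks only
  out2 <- correlation_with_p(x, exp(x), "spearman")
  expect_equal(out2$r, 1)
  # hand-computed Spearman: d^2 total = 4 -> 1 - 24/120
  out3 <- correlation_with_p(x, c(2, 1, 4, 3, 5), "spearman")
  expect_equal(out3$r, 0.8, tolerance = 1e-12)
  # zero variance is NA, short vectors are errors
  expect_true(is.na(correlation_with_p(rep(1, 5), x, "pearson")$r))
  expect_error(correlation_with_p(1:3, 1:3), "n >= 4")
  # cor.test is the oracle for the t-approximation p
  set.seed(41)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    ct <- cor.test(a, b)
    mine <- correlation_with_p(a, b, "pearson")
    expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    r0 <- correlation_with_p(x, y, "spearman")$r
    r1 <- correlation_with_p(exp(x), y^3 + y, "spearman")$r
    expect_equal(r0, r1, tolerance = 1e-12)
  }
})

test_that("AFRT selection keeps anchors and screens serum indices", {
  ph <- generate_phenotypes(10, seed = 1)$phenotypes
  out <- select_afrt(ph)
  expect_true(all(c("AFW", "AFP") %in% out$traits))
  # a trait identical to AFP is always selected with r = 1
  ph$mirror <- ph$AFP
  out2 <- select_afrt(ph)
  expect_true("mirror" %in% out2$traits)
  expect_equal(out2$table$r_afp[out2$table$trait == "mirror"], 1)
  # constant traits are excluded with a warning
  ph$flat <- 5
  expect_warning(out3 <- select_afrt(ph), "constant")
  expect_false("flat" %in% out3$traits)
  expect_error(select_afrt(ph[1:4, ]), ">= 6")
})

test_that("serum traits independent of adiposity are usually excluded", {
  # make TG truly null: no planted coupling and no line difference
  pp <- phenotype_params()
  pp$fat_mean[pp$trait == "TG"] <- pp$lean_mean[pp$trait == "TG"]
  pp$fat_sd[pp$trait == "TG"] <- pp$lean_sd[pp$trait == "TG"]
  excl <- vapply(1:20, function(s) {
    ph <- generate_phenotypes(10, pp, seed = 100 + s)$phenotypes
    !"TG" %in% select_afrt(ph)$traits
  }, logical(1))
  expect_gte(mean(excl), 0.8)
})

test_that("soft-power selection satisfies the scale-free criterion", {
  des <- make_two_group_design(10)
  ts <- list(modules = list(
    list(name = "A", genes = sprintf("hg%04d", 1:100), loading = 0.8,
         latent = NA, afp_cor = 0),
    list(name = "B", genes = sprintf("hg%04d", 101:200), loading = 0.8,
         latent = NA, afp_cor = 0),
    list(name = "C", genes = sprintf("hg%04d", 201:300), loading = 0.8,
         latent = NA, afp_cor = 0)))
  for (s in 1:3) {
    ex <- generate_expression(des, n_genes = 400, truth_spec = ts, seed = s)
    expr <- t(normalized_expression(
      ex$counts[, des$sample_id[des$compartment == "duodenum"]]))
    sp <- suppressMessages(pick_soft_power(expr))
    expect_true(sp$power %in% c(1:10, 12, 14, 16))
    expect_gte(sp$table$rsq[sp$table$power == sp$power], 0.8)
  }
  # mean connectivity decreases weakly in the power (a <= 1)
  set.seed(43)
  X <- matrix(rnorm(20 * 60), 20, 60)
  tab <- suppressMessages(pick_soft_power(X))$table
  expect_true(all(diff(tab$mean_k) <= 1e-12))
  # random independent genes show weak scale-free fit at power 1
  expect_lt(tab$rsq[tab$power == 1], 0.8)
})

test_that("topological overlap is a bounded unit-diagonal similarity", {
  set.seed(44)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    tom <- tom_similarity(a)
    expect_true(isSymmetric(tom, tol = 1e-12))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, n))
  }
})

test_that("planted modules are recovered and merged when redundant", {
  skip_if_not_installed("mclust")
  des <- make_two_group_design(10)
  ts <- list(modules = list(
    list(name = "A", genes = sprintf("hg%04d", 1:100), loading = 0.8,
         latent = NA, afp_cor = 0),
    list(name = "B", genes = sprintf("hg%04d", 101:200), loading = 0.8,
         latent = NA, afp_cor = 0),
    list(name = "C", genes = sprintf("hg%04d", 201:300), loading = 0.8,
         latent = NA, afp_cor = 0)))
  ex <- generate_expression(des, n_genes = 400, truth_spec = ts, seed = 2)
  expr <- t(normalized_expression(
    ex$counts[, des$sample_id[des$compartment == "jejunum"]]))
  sp <- suppressMessages(pick_soft_power(expr))
  mod <- build_modules(expr, sp$power)
  truth <- ex$truth$module_membership[colnames(expr)]
  truth[is.na(truth)] <- "grey"
  ari <- mclust::adjustedRandIndex(truth, mod$membership)
  expect_gt(ari, 0.8)
  # eigengenes have unit variance; kME is defined for assigned genes
  expect_equal(unname(apply(mod$eigengenes, 2, sd)),
               rep(1, ncol(mod$eigengenes)), tolerance = 1e-9)
  assigned <- names(mod$membership)[mod$membership != "grey"]
  expect_false(any(is.na(mod$kme[assigned, ])))
})

test_that("two perfectly correlated planted modules merge into one", {
  set.seed(45)
  n <- 24
  f <- rnorm(n)
  expr <- cbind(
    sapply(1:40, function(i) 0.95 * f + 0.31 * rnorm(n)),
    sapply(1:40, function(i) 0.95 * f + 0.31 * rnorm(n)),
    matrix(rnorm(n * 40), n)
  )
  colnames(expr) <- paste0("g", seq_len(ncol(expr)))
  rownames(expr) <- paste0("s", 1:n)
  mod <- build_modules(expr, 6)
  big <- setdiff(unique(mod$membership[1:80]), "grey")
  expect_equal(length(big), 1)
})

test_that("genes matching their eigengene pass the AFRT screen", {
  set.seed(46)
  n <- 20
  f <- rnorm(n)
  expr <- sapply(1:60, function(i) 0.9 * f + sqrt(1 - 0.81) * rnorm(n))
  expr <- cbind(expr, matrix(rnorm(n * 60), n))
  colnames(expr) <- paste0("g", 1:120)
  rownames(expr) <- paste0("s", 1:n)
  mod <- build_modules(expr, 6, min_module_size = 20)
  traits <- cbind(T1 = f + 0.3 * rnorm(n))
  rownames(traits) <- rownames(expr)
  sc <- screen_genes(mod, expr, traits)
  m1 <- mod$membership["g1"]
  expect_true(m1 %in% sc$modules_selected)
  expect_true("g1" %in% sc$gene_set)
  # the strongest loaders carry hub flags
  expect_true(any(sc$genes$hub))
})

test_that("microbe screening respects restriction and detects coupling", {
  set.seed(47)
  n <- 20
  afp <- rnorm(n)
  sp <- rbind(
    coupled = exp(1.5 * afp + 0.5 * rnorm(n)),
    null1 = exp(rnorm(n)),
    null2 = exp(rnorm(n))
  )
  sp <- sweep(sp, 2, colSums(sp), `/`)
  colnames(sp) <- paste0("s", 1:n)
  traits <- cbind(AFP = afp)
  rownames(traits) <- colnames(sp)
  out <- screen_microbes(sp, traits)
  expect_true("coupled" %in% out$species)
  out2 <- screen_microbes(sp, traits, restrict_to = c("null1"))
  expect_false("coupled" %in% out2$species)
  expect_warning(out3 <- screen_microbes(sp, traits, restrict_to = "zz"),
                 "disjoint")
  expect_length(out3$species, 0)
})

test_that("cross-omic records obey the DEG filter and threshold nesting", {
  set.seed(48)
  n <- 20
  f <- rnorm(n)
  sp <- rbind(spA = exp(2 * f + 0.3 * rnorm(n)))
  sp <- rbind(sp, spB = exp(rnorm(n)))
  colnames(sp) <- paste0("s", 1:n)
  expr <- cbind(gene1 = 2 * f + 0.3 * rnorm(n),
                gene2 = 2 * f + 0.3 * rnorm(n),
                gene3 = rnorm(n))
  rownames(expr) <- colnames(sp)
  deg <- data.frame(gene_id = c("gene1", "gene2", "gene3"),
                    log2fc = c(2, 2, 0.1),
                    is_deg = c(TRUE, FALSE, FALSE))
  # gene2 correlates strongly but fails the DEG filter -> never appears
  rec <- cross_omic_associations(c("spA", "spB"), c("gene1", "gene2"),
                                 deg, sp, expr, "jejunum")
  expect_false("gene2" %in% rec$gene)
  expect_true("gene1" %in% rec$gene)
  expect_equal(attr(rec, "p_threshold"), 0.05)
  # ceca threshold returns a subset of the small-intestine records
  rec_ceca <- cross_omic_associations(c("spA", "spB"), c("gene1", "gene2"),
                                      deg, sp, expr, "ceca")
  expect_equal(attr(rec_ceca, "p_threshold"), 0.01)
  expect_true(all(paste(rec_ceca$species, rec_ceca$gene) %in%
                    paste(rec$species, rec$gene)))
  # misaligned samples are a hard error
  expr_bad <- expr
  rownames(expr_bad)[1] <- "other"
  expect_error(cross_omic_associations("spA", "gene1", deg, sp, expr_bad,
                                       "jejunum"), "misaligned")
})

test_that("the cascade is deterministic given inputs and seed", {
  sim <- simulate_study(seed = 3, n_species = 80, n_genes_per_species = 5,
                        n_host_genes = 600, depth = 3e4)
  r1 <- suppressMessages(run_association_cascade(sim, "ceca",
                                                 n_top_genes = 300,
                                                 seed = 3))
  r2 <- suppressMessages(run_association_cascade(sim, "ceca",
                                                 n_top_genes = 300,
                                                 seed = 3))
  expect_identical(r1$associations, r2$associations)
  expect_identical(r1$modules$membership, r2$modules$membership)
})
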