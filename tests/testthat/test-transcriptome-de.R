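# Negative-binomial differential expression, DEG calling, qPCR
# concordance and hypergeometric enrichment.

test_that("size factors recover scalings, identity and planted depths", {
  set.seed(31)
  base <- matrix(rpois(200 * 4, 50), 200, 4)
  colnames(base) <- paste0("s", 1:4)
  # sample 2 = exact doubling of sample 1
  cnt <- base
  cnt[, 2] <- cnt[, 1] * 2L
  sf <- size_factors(cnt)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
  # identical samples
  same <- base
  same[, 2:4] <- same[, 1]
  expect_equal(unname(size_factors(same)), rep(1, 4), tolerance = 1e-12)
  # planted depths recovered within 5%
  depths <- c(0.5, 1, 2, 4)
  mu <- outer(2^rnorm(3000, 7, 1.5), depths)
  cnt2 <- matrix(rnbinom(length(mu), mu = mu, size = 20), nrow(mu))
  colnames(cnt2) <- paste0("s", 1:4)
  sf2 <- size_factors(cnt2)
  target <- depths / exp(mean(log(depths)))
  expect_true(all(abs(sf2 / target - 1) < 0.05))
})

test_that("size-factor fallback engages when no gene is always positive", {
  set.seed(32)
  cnt <- matrix(rpois(100 * 4, 3), 100, 4)
  for (j in 1:4) cnt[sample(100, 40), j] <- 0L  # every gene hit somewhere
  cnt[rowSums(cnt == 0) == 0, 1] <- 0L
  colnames(cnt) <- paste0("s", 1:4)
  expect_warning(sf <- size_factors(cnt), "positive-count")
  expect_true(all(is.finite(sf) & sf > 0))
})

test_that("log2FC estimates are depth-invariant and label-equivariant", {
  set.seed(33)
  G <- 300
  mu0 <- 2^rnorm(G, 6, 1)
  lfc <- rnorm(G, 0, 1)
  cnt <- cbind(
    matrix(rnbinom(G * 6, mu = mu0 * 2^(lfc / 2), size = 20), G, 6),
    matrix(rnbinom(G * 6, mu = mu0 * 2^(-lfc / 2), size = 20), G, 6)
  )
  rownames(cnt) <- paste0("g", 1:G)
  colnames(cnt) <- paste0("s", 1:12)
  groups <- rep(c("lean", "fat"), each = 6)
  de1 <- nb_fit_and_test(cnt, groups)
  # at fixed dispersions the GLM stage is scale-equivariant up to the
  # (small) non-equivariance of the NB score equations themselves
  disp <- estimate_dispersions(cnt, groups)
  de2 <- nb_fit_and_test(cnt * 2L, groups, dispersions = disp)
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 0.005)
  # with re-estimated dispersions the estimates move only marginally
  de2b <- nb_fit_and_test(cnt * 2L, groups)
  expect_equal(de1$log2fc, de2b$log2fc, tolerance = 0.02)
  # swapping the two lines negates every log2FC and keeps p
  sw <- c("lean" = "fat", "fat" = "lean")[groups]
  de3 <- nb_fit_and_test(cnt, unname(sw))
  expect_equal(de1$log2fc, -de3$log2fc, tolerance = 1e-9)
  expect_equal(de1$p, de3$p, tolerance = 1e-9)
})

test_that("size factors and fold changes agree with the DESeq2 reference", {
  skip_if_not_installed("DESeq2")
  set.seed(34)
  G <- 400
  mu0 <- 2^rnorm(G, 7, 1.2)
  lfc <- c(rnorm(40, 0, 2), rep(0, G - 40))
  sfT <- exp(rnorm(10, 0, 0.3))
  mu <- outer(mu0, sfT) *
    2^(outer(lfc / 2, c(rep(1, 5), rep(-1, 5))))
  cnt <- matrix(rnbinom(G * 10, mu = mu, size = 10), G, 10)
  rownames(cnt) <- paste0("g", 1:G)
  colnames(cnt) <- paste0("s", 1:10)
  groups <- rep(c("lean", "fat"), each = 5)
  sf <- size_factors(cnt)
  ref_sf <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  expect_equal(sf / ref_sf, rep(mean(sf / ref_sf), 10),
               tolerance = 1e-8, ignore_attr = TRUE)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      cnt, data.frame(line = factor(groups, c("fat", "lean"))), ~line)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  mine <- nb_fit_and_test(cnt, groups, sf)
  keep <- !is.na(res$log2FoldChange) & abs(res$log2FoldChange) > 0.5
  expect_gt(cor(mine$log2fc[keep], res$log2FoldChange[keep]), 0.97)
})

test_that("all-zero genes report NA and are excluded from the correction", {
  set.seed(35)
  cnt <- matrix(rpois(50 * 8, 40), 50, 8)
  cnt[7, ] <- 0L
  rownames(cnt) <- paste0("g", 1:50)
  colnames(cnt) <- paste0("s", 1:8)
  de <- suppressWarnings(
    nb_fit_and_test(cnt, rep(c("lean", "fat"), each = 4)))
  expect_true(is.na(de$p[7]) && is.na(de$q[7]))
  expect_equal(suppressWarnings(bh_fdr(de$p)), de$q)
})

test_that("DEG calling applies both thresholds strictly", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(1.51, 1.5, 3, -2),
                    q = c(0.049, 0.049, 0.05, 0.01))
  out <- call_degs(res)
  expect_identical(out$is_deg, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(attr(out, "n_up"), 1L)
  expect_identical(attr(out, "n_down"), 1L)
  # cross-compartment intersection table
  two <- call_degs(list(duodenum = res, jejunum = res))
  inter <- attr(two, "intersection")
  expect_identical(inter$n_deg[inter$compartments == "all"], 2L)
})

test_that("ddCt fold changes and concordance follow the 2^-ddCt method", {
  ct <- rbind(geneA = c(25, 25.2, 24.8, 27, 27.2, 26.8))
  ref <- rep(20, 6)
  groups <- rep(c("g1", "g2"), each = 3)
  out <- ddct_log2fc(ct, ref, groups)
  expect_equal(unname(out$log2fc), -2, tolerance = 1e-9)
  expect_equal(2^unname(out$log2fc), 0.25, tolerance = 1e-9)
  # identical groups give zero
  ct0 <- rbind(g = rep(24, 6))
  expect_equal(unname(ddct_log2fc(ct0, ref, groups)$log2fc), 0)
  # perfect concordance with the RNA-seq vector
  ct2 <- rbind(a = c(25, 25, 25, 27, 27, 27),
               b = c(30, 30, 30, 28.5, 28.5, 28.5))
  res <- ddct_log2fc(ct2, ref, groups,
                     rnaseq_log2fc = c(a = -2, b = 1.5))
  expect_equal(res$pearson_r, 1, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_error(ddct_log2fc(ct, c(ref[-1], NA), groups), "reference")
})

test_that("hypergeometric enrichment matches the closed-form sum", {
  map <- data.frame(gene_id = paste0("g", 1:100),
                    pathway_id = rep(c("pwA", rep("pwB", 9)), 10))
  map$pathway_id[1:10] <- "pwA"
  map$pathway_id[11:100] <- "pwB"
  bg <- paste0("g", 1:100)
  deg <- c(paste0("g", 1:5), paste0("g", 96:100))  # 5 in pwA, 5 in pwB
  out <- pathway_enrichment(deg, bg, map)
  pA <- out$p[out$pathway_id == "pwA"]
  # closed-form upper tail: sum_{x=5..10} C(10,x) C(90,10-x) / C(100,10)
  oracle <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) / choose(100, 10)
  expect_equal(pA, oracle, tolerance = 1e-12)
  expect_equal(pA, 1.60e-3, tolerance = 0.01)
  expect_equal(out$rich_factor[out$pathway_id == "pwA"], 0.5)
})

test_that("enrichment degenerate cases follow the definitions", {
  map <- data.frame(gene_id = paste0("g", 1:20),
                    pathway_id = c(rep("pwA", 5), rep("pwB", 15)))
  bg <- paste0("g", 1:20)
  out <- pathway_enrichment(paste0("g", 6:9), bg, map)
  expect_equal(out$p[out$pathway_id == "pwA"], 1)          # k = 0
  expect_equal(out$rich_factor[out$pathway_id == "pwA"], 0)
  # pathway covering the whole background
  map2 <- data.frame(gene_id = bg, pathway_id = "all")
  out2 <- pathway_enrichment(paste0("g", 1:4), bg, map2)
  expect_equal(out2$p, 1)
  expect_equal(out2$rich_factor, 4 / 20)
  expect_warning(res <- pathway_enrichment(character(0), bg, map), "empty")
  expect_equal(nrow(res), 0)
  expect_error(pathway_enrichment("zz", bg, map), "subset")
})
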