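test_that("site_stats evaluates H and PIC correctly across the frequency range", {
  # p = 0.5: two samples 0/1 -> H = 0.5, PIC = 0.375 (the analytic maximum)
  tab <- toy_table(rbind(
    c(1L, 1L),   # p = 0.5
    c(2L, 2L),   # p = 1, monomorphic
    rep(NA_integer_, 2)
  ))
  ss <- site_stats(tab)
  expect_equal(ss$H[1], 0.5)
  expect_equal(ss$PIC[1], 0.375)
  expect_equal(ss$H[2], 0)
  expect_equal(ss$PIC[2], 0)
  # all-missing site is NA, not zero
  expect_true(is.na(ss$H[3]) && is.na(ss$PIC[3]))
  # direct evaluation at p = 0.1
  expect_equal(het_expected(0.1), 0.18)
  expect_equal(pic(0.1), 0.1638)
})

test_that("PIC <= H everywhere, both peak at p = 0.5, PIC increases in MAF", {
  p <- seq(0, 1, by = 0.001)
  expect_true(all(pic(p) <= het_expected(p) + 1e-12))
  expect_equal(p[which.max(het_expected(p))], 0.5)
  expect_equal(p[which.max(pic(p))], 0.5)
  expect_equal(max(het_expected(p)), 0.5)
  expect_equal(max(pic(p)), 0.375)
  maf <- seq(0.001, 0.5, by = 0.001)
  expect_true(all(diff(pic(maf)) > 0))
})

test_that("windowed pi matches the per-site formula and conserves mass", {
  # one site, 2 diploid samples, both het: j = 2, c = 4 -> pi_s = 1/3
  tab <- toy_table(matrix(c(1L, 1L), 1, 2), pos0 = 500L)
  w <- windowed_pi(tab, window = 1000L, chrom_lengths = c(chr1 = 2000L))
  expect_equal(w$pi[1], (2 * 2 * 2 / 12) / 1000)
  expect_equal(w$pi[2], 0) # window with no variants
  # conservation: sum over windows of pi * window = sum of per-site pi
  set.seed(3)
  g <- simulate_reference(c(chr1 = 20000), seed = 3)
  sim <- simulate_cohort(g, n_samples = 10, n_sites = 50, n_groups = 1,
                         missing_rate = 0.2, seed = 3)
  w <- windowed_pi(sim$table, window = 1000L, chrom_lengths = chrom_lengths(g))
  c_al <- 2 * rowSums(!is.na(sim$table$gt))
  j <- rowSums(sim$table$gt, na.rm = TRUE)
  per_site <- ifelse(c_al >= 2, 2 * j * (c_al - j) / (c_al * (c_al - 1)), 0)
  expect_equal(sum(w$pi * 1000), sum(per_site))
  # windows tile without overlap
  expect_true(all(w$start0[-1] - head(w$end0, -1) %in% c(0L, -18000L)))
})

test_that("tstv classifies substitutions and flags undefined ratios", {
  s <- data.frame(ref = c("C", "G", "C"), alt = c("T", "A", "A"))
  r <- tstv(s)
  expect_equal(r$ratio, 2)
  expect_equal(tstv(data.frame(ref = c("A", "C"), alt = c("C", "G")))$ratio, 0)
  r0 <- tstv(data.frame(ref = "A", alt = "G"))
  expect_true(r0$undefined && is.na(r0$ratio))
  # non-SNP records are skipped with a count
  r2 <- tstv(data.frame(ref = c("A", "AT"), alt = c("G", "A")))
  expect_equal(r2$n_skipped, 1L)
  # binomial simulation: ts drawn with probability 2/3 -> ratio near 2
  set.seed(11)
  g <- simulate_reference(c(chr1 = 1e5), seed = 11)
  sim <- simulate_cohort(g, n_samples = 4, n_sites = 1000, n_groups = 1,
                         ts_prob = 2 / 3, seed = 11)
  expect_equal(tstv(sim$table)$ratio, 2, tolerance = 0.25)
})

test_that("sample heterozygosity is the percent of het calls among called sites", {
  tab <- toy_table(cbind(c(1L, 1L, 0L, 2L), c(0L, 0L, 2L, 2L), c(NA, NA, NA, NA)))
  h <- sample_heterozygosity(tab)
  expect_equal(unname(h[1]), 50)
  expect_equal(unname(h[2]), 0)
  expect_true(is.na(h[3]))
  # parameter recovery: per-sample het rate 5% within binomial error
  set.seed(19)
  gt <- matrix(rbinom(2000 * 10, 1, 0.05), 2000, 10)
  tab <- toy_table(gt)
  expect_equal(mean(sample_heterozygosity(tab)), 5, tolerance = 0.25)
})

test_that("SNP spacing summary follows the length/count definition", {
  s <- snp_spacing_summary(c(chr1 = 10), c(chr1 = 100000))
  expect_equal(s$mean_spacing_bp, 10000)
  s2 <- snp_spacing_summary(list(chr1 = c(5, 50, 900)), c(chr1 = 1000))
  expect_equal(s2$max_gap_bp, 850)
  expect_warning(
    s3 <- snp_spacing_summary(c(chr1 = 10, chr2 = 0), c(chr1 = 1e5, chr2 = 1e5)),
    "0 SNPs"
  )
  expect_equal(nrow(s3), 1L)
  # cross-chromosome mean is unweighted
  s4 <- snp_spacing_summary(c(chr1 = 10, chr2 = 1), c(chr1 = 1e5, chr2 = 1e5))
  expect_equal(attr(s4, "cross_chrom_mean_bp"), mean(c(1e4, 1e5)))
})

test_that("FST attains its exact limits and is label-symmetric", {
  # two groups fixed for alternate alleles -> FST = 1
  gt <- cbind(matrix(0L, 20, 6), matrix(2L, 20, 6))
  tab <- toy_table(gt)
  grp <- factor(rep(c("a", "b"), each = 6))
  f <- pairwise_fst(tab, grp)
  expect_equal(unname(f$fst["a", "b"]), 1)
  expect_equal(f$fst, t(f$fst))
  expect_equal(diag(f$fst), c(a = 0, b = 0))
  # identical genotype distributions in both groups -> estimate near 0
  set.seed(23)
  gt2 <- matrix(rbinom(100 * 80, 2, 0.4), 100, 80)
  gt2 <- cbind(gt2, gt2) # group b duplicates group a exactly
  f2 <- pairwise_fst(toy_table(gt2), factor(rep(c("a", "b"), each = 80)))
  expect_lt(abs(f2$fst["a", "b"]), 0.02)
})

test_that("random labels on a panmictic cohort give FST near zero", {
  set.seed(29)
  gt <- matrix(rbinom(300 * 60, 2, runif(300, 0.1, 0.9)), 300, 60)
  tab <- toy_table(gt)
  ests <- replicate(20, {
    grp <- factor(sample(rep(c("a", "b"), each = 30)))
    pairwise_fst(tab, grp)$fst["a", "b"]
  })
  expect_lt(abs(mean(ests)), 0.01)
})

test_that("Hudson and Weir-Cockerham agree on strongly diverged fixtures", {
  set.seed(37)
  g <- simulate_reference(c(chr1 = 1e5), seed = 37)
  sim <- simulate_cohort(g, n_samples = 100, n_sites = 1500, n_groups = 2,
                         fst = 0.3, missing_rate = 0, seed = 37)
  fh <- pairwise_fst(sim$table, sim$groups, "hudson")$fst[1, 2]
  fw <- pairwise_fst(sim$table, sim$groups, "wc")$fst[1, 2]
  expect_equal(fh, 0.3, tolerance = 0.05 / 0.3)
  expect_equal(fw, fh, tolerance = 0.15)
})

test_that("IBS kinship matches hand computation and its limits", {
  tab <- toy_table(rbind(c(0L, 0L, 2L), c(1L, 1L, 1L), c(2L, 2L, 0L), c(0L, NA, 2L)))
  K <- ibs_kinship(tab)$K
  expect_equal(diag(K), setNames(rep(1, 3), colnames(K)))
  # samples 1 and 2: identical over shared called sites 1-3 -> 1
  expect_equal(unname(K[1, 2]), 1)
  # samples 1 and 3 by hand: sites (0,2),(1,1),(2,0),(0,2) -> (0+1+0+0)/4
  expect_equal(unname(K[1, 3]), 0.25)
  # all-0 vs all-2 -> 0
  tab2 <- toy_table(rbind(c(0L, 2L), c(0L, 2L)))
  expect_equal(unname(ibs_kinship(tab2)$K[1, 2]), 0)
  expect_equal(K, t(K))
})

test_that("PCA separates duplicated clusters and reports valid variance fractions", {
  set.seed(41)
  a <- rbinom(100, 2, 0.2)
  b <- rbinom(100, 2, 0.8)
  gt <- cbind(a, a, a, b, b, b)
  noise <- matrix(rbinom(100 * 6, 2, 0.5), 100, 6) # one extra polymorphic row set
  tab <- toy_table(gt)
  pc <- genotype_pca(tab, 2)
  # PC1 separates the two duplicated clusters and explains ~100% of variance
  expect_true(all(sign(pc$scores[1:3, 1]) != sign(pc$scores[4:6, 1])))
  expect_gt(pc$explained[1], 0.999)
  expect_true(all(diff(pc$sdev) <= 1e-9))
  expect_lte(sum(pc$explained), 1)
  expect_error(genotype_pca(toy_table(matrix(1L, 5, 3)), 2), "no variance")
  expect_error(genotype_pca(tab, 10), "exceeds")
})

test_that("full-rank PCA scores preserve pairwise sample distances", {
  set.seed(43)
  gt <- matrix(rbinom(200 * 8, 2, runif(200, 0.2, 0.8)), 200, 8)
  tab <- toy_table(gt)
  pc <- genotype_pca(tab, 7)
  g <- t(tab$gt)
  g <- sweep(g, 2, colMeans(g))
  expect_equal(unname(as.matrix(dist(pc$scores))), unname(as.matrix(dist(g))),
               tolerance = 1e-8)
})
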