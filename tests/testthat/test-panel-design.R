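test_that("minor-allele-count filter follows the het/hom counting rule", {
  # one hom-alt + one het (alt count 3 of 6) and three hets both reach mac 3
  tab <- toy_table(rbind(c(2, 1, 0), c(1, 1, 1), c(0, 0, 1)))
  kept <- filter_by_allele_count(tab, min_mac = 3)
  expect_equal(kept$sites$pos0, tab$sites$pos0[1:2])
  # mac is the MINOR count: near-fixed site has mac 1
  tab2 <- toy_table(matrix(c(1, 0, 0, 0, 0), nrow = 1))
  expect_equal(n_sites(filter_by_allele_count(tab2, 3)), 0L)
  tab3 <- toy_table(matrix(c(2, 2, 2, 1, 0), nrow = 1)) # alt 7/10, minor = 3
  expect_equal(n_sites(filter_by_allele_count(tab3, 3)), 1L)
})

test_that("all-missing sites are excluded with a warning", {
  tab <- toy_table(rbind(c(NA, NA, NA), c(1, 1, 1)))
  expect_warning(kept <- filter_by_allele_count(tab, 3), "zero called")
  expect_equal(n_sites(kept), 1L)
})

test_that("gene-space extension is strand-aware, clipped and merged", {
  lens <- c(chr1 = 100000L)
  plus <- data.frame(gene_id = "g1", chrom = "chr1", start0 = 10000L,
                     end0 = 12000L, strand = "+", stringsAsFactors = FALSE)
  gs <- gene_space_df(build_gene_space(plus, lens))
  expect_equal(gs$start0, 5000L)
  expect_equal(gs$end0, 13000L)
  minus <- plus
  minus$strand <- "-"
  gs <- gene_space_df(build_gene_space(minus, lens))
  expect_equal(gs$start0, 9000L)
  expect_equal(gs$end0, 17000L)
  # clipping at the chromosome start
  near0 <- data.frame(gene_id = "g2", chrom = "chr1", start0 = 2000L,
                      end0 = 3000L, strand = "+", stringsAsFactors = FALSE)
  gs <- gene_space_df(build_gene_space(near0, lens))
  expect_equal(gs$start0, 0L)
  expect_equal(gs$end0, 4000L)
  # overlapping extensions merge into one interval
  two <- rbind(plus, data.frame(gene_id = "g3", chrom = "chr1", start0 = 13500L,
                                end0 = 14000L, strand = "+", stringsAsFactors = FALSE))
  gs <- gene_space_df(build_gene_space(two, lens))
  expect_equal(nrow(gs), 1L)
  expect_equal(gs$end0, 15000L)
  expect_error(build_gene_space(data.frame(gene_id = "gX", chrom = "chrZ",
                                           start0 = 0L, end0 = 10L, strand = "+"),
                                lens), "unknown chromosome")
})

test_that("variant classification respects half-open boundaries and matches brute force", {
  lens <- c(chr1 = 100000L)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start0 = 10000L,
                      end0 = 12000L, strand = "+", stringsAsFactors = FALSE)
  gs <- build_gene_space(genes, lens) # [5000, 13000)
  tab <- toy_table(matrix(1, nrow = 2, ncol = 2), pos0 = c(5000L, 13000L))
  lab <- classify_variants(tab, gs)$sites$class
  expect_equal(lab, c("genic", "intergenic"))
  # brute-force point-in-interval oracle on random positions
  set.seed(42)
  pos <- sort(sample.int(100000L, 50L)) - 1L
  tab <- toy_table(matrix(1, nrow = 50, ncol = 2), pos0 = pos)
  lab <- classify_variants(tab, gs)$sites$class
  expected <- ifelse(pos >= 5000 & pos < 13000, "genic", "intergenic")
  expect_equal(lab, expected)
})

test_that("variants on chromosomes absent from the gene space become intergenic with warning", {
  lens <- c(chr1 = 100000L)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start0 = 0L,
                      end0 = 100000L, strand = "+", stringsAsFactors = FALSE)
  gs <- build_gene_space(genes, lens, up = 0, down = 0)
  tab <- toy_table(matrix(1, nrow = 2, ncol = 2), chrom = c("chr1", "chrZ"),
                   pos0 = c(10L, 10L))
  expect_warning(out <- classify_variants(tab, gs), "absent")
  expect_equal(out$sites$class[out$sites$chrom == "chrZ"], "intergenic")
})

test_that("greedy target selection reproduces the hand-worked example", {
  tab <- toy_table(matrix(1, nrow = 5, ncol = 4),
                   pos0 = c(0L, 1000L, 3000L, 3500L, 7000L))
  tab$sites$class <- "genic"
  sel <- select_targets(tab, d_genic = 3000)
  expect_equal(sel$pos0, c(0L, 3000L, 7000L))
  # single candidate is always selected
  tab1 <- toy_table(matrix(1, nrow = 1, ncol = 4))
  tab1$sites$class <- "intergenic"
  expect_equal(nrow(select_targets(tab1)), 1L)
})

test_that("greedy selection attains the exhaustive maximum on random instances", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:14, 1)
    pos <- sort(sample.int(20000L, n)) - 1L
    dmin <- sample(c(500L, 1500L, 3000L), 1)
    tab <- toy_table(matrix(1, nrow = n, ncol = 4), pos0 = pos)
    tab$sites$class <- "genic"
    sel <- select_targets(tab, d_genic = dmin)
    expect_equal(nrow(sel), max_spaced_subset(pos, dmin))
    expect_true(all(diff(sel$pos0) >= dmin))
  }
})

test_that("classes are spaced independently and the cap thins deterministically", {
  pos <- c(0L, 100L, 3200L, 3300L, 6400L, 6500L)
  tab <- toy_table(matrix(1, nrow = 6, ncol = 4), pos0 = pos)
  tab$sites$class <- rep(c("genic", "intergenic"), 3)
  sel <- select_targets(tab, d_genic = 3000, d_intergenic = 3000)
  # both classes keep all three of their members despite cross-class proximity
  expect_equal(nrow(sel), 6L)
  capped <- select_targets(tab, d_genic = 3000, d_intergenic = 3000, cap = 4)
  expect_equal(nrow(capped), 4L)
  # thinning drops the right member of the closest same-class pair first,
  # so reruns are identical
  capped2 <- select_targets(tab, d_genic = 3000, d_intergenic = 3000, cap = 4)
  expect_identical(capped, capped2)
})

test_that("round-1 probe placement centers the target in the capture window", {
  g <- simulate_reference(c(chr1 = 10000), seed = 123)
  p <- design_probe("chr1", 1000L, g, L = 40L, W = 460L)
  expect_equal(p$probe_start0, 730L)
  expect_equal(p$probe_end0, 770L)
  expect_equal(p$probe_strand, "+")
  expect_equal(p$design_round, 1L)
  expect_equal(p$uniqueness_count, 1L)
  expect_equal(p$probe_seq,
               as.character(Biostrings::subseq(g[["chr1"]], 731, 770)))
})

test_that("duplicated round-1 k-mer forces a round-2 rescue that is unique", {
  set.seed(9)
  g <- simulate_reference(c(chr1 = 10000), seed = 9)
  seqs <- as.character(g)
  # duplicate the exact round-1 probe 40-mer [730, 770) elsewhere
  kmer <- substr(seqs[["chr1"]], 731, 770)
  substr(seqs[["chr1"]], 5001, 5040) <- kmer
  g2 <- toy_genome(chr1 = seqs[["chr1"]])
  p <- design_probe("chr1", 1000L, g2, L = 40L, W = 460L)
  expect_equal(p$design_round, 2L)
  expect_equal(probe_uniqueness(p$probe_seq, g2), 1L)
  # capture-window invariant
  if (p$probe_strand == "+") {
    expect_true(p$probe_end0 <= 1000 && 1000 < p$probe_end0 + 460)
  } else {
    expect_true(p$probe_start0 - 460 <= 1000 && 1000 < p$probe_start0)
  }
})

test_that("a target at the chromosome start is rescued on the minus strand or rejected", {
  g <- simulate_reference(c(chr1 = 10000), seed = 21)
  p <- design_probe("chr1", 10L, g, L = 40L, W = 460L)
  expect_false(is.null(p))
  expect_equal(p$probe_strand, "-")
  expect_true(p$probe_start0 - 460 <= 10 && 10 < p$probe_start0)
})

test_that("probe_uniqueness counts both strands and matches a naive scan", {
  s1 <- paste(rep("ACGTT", 200), collapse = "")
  expect_error(probe_uniqueness("ACGTN", toy_genome(chr1 = s1)), "A,C,G,T")
  set.seed(31)
  g <- simulate_reference(c(chr1 = 2500, chr2 = 2500), seed = 31)
  chroms <- as.character(g)
  kmer <- substr(chroms[["chr1"]], 101, 140)
  expect_equal(probe_uniqueness(kmer, g), naive_kmer_count(kmer, chroms))
  # copy onto second chromosome -> count 2
  chroms2 <- chroms
  substr(chroms2[["chr2"]], 201, 240) <- kmer
  g2 <- toy_genome(chr1 = chroms2[["chr1"]], chr2 = chroms2[["chr2"]])
  expect_equal(probe_uniqueness(kmer, g2), 2L)
  expect_equal(probe_uniqueness(kmer, g2), naive_kmer_count(kmer, as.character(g2)))
  # reverse complement occurrences are counted too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
  expect_equal(probe_uniqueness(rc, g2), 2L)
})

test_that("panel QC reports spacing, gap fraction and max gap per the definitions", {
  probes <- data.frame(
    target_id = sprintf("T%d", 1:2), chrom = "chr1", pos0 = c(0L, 100000L),
    class = c("genic", "genic"), probe_start0 = c(0L, 0L), probe_end0 = c(40L, 40L),
    probe_strand = "+", probe_seq = "A", design_round = 1L,
    stringsAsFactors = FALSE
  )
  panel <- structure(list(probes = probes), class = "spet_panel")
  qc <- panel_qc(panel, c(chr1 = 1000000L))
  expect_equal(qc$mean_interprobe_spacing_kbp, 500)
  expect_equal(qc$max_gap_bp, 100000L)
  expect_equal(qc$fraction_gaps_over_50kbp, 1)
  # hand-enumerated gap fraction on a 5-target toy: gaps 10, 60k, 10, 60k
  probes5 <- probes[rep(1, 5), ]
  probes5$pos0 <- c(0L, 10L, 60010L, 60020L, 120020L)
  probes5$target_id <- sprintf("T%d", 1:5)
  qc5 <- panel_qc(structure(list(probes = probes5), class = "spet_panel"),
                  c(chr1 = 1000000L))
  expect_equal(qc5$fraction_gaps_over_50kbp, 0.5)
  expect_equal(qc5$n_genic + qc5$n_intergenic, qc5$n_targets)
})

test_that("designed panels satisfy spacing and probe invariants end to end", {
  g <- simulate_reference(c(chr1 = 40000, chr2 = 30000), seed = 77)
  genes <- simulate_genes(g, density = 1 / 4000, seed = 77)
  sim <- simulate_cohort(g, n_samples = 30, n_sites = 150, n_groups = 1, seed = 77)
  panel <- design_panel(sim$table, genes, g, d_genic = 800, d_intergenic = 3000)
  p <- panel$probes
  expect_gt(nrow(p), 5L)
  for (ch in unique(p$chrom)) {
    for (cl in unique(p$class)) {
      pos <- sort(p$pos0[p$chrom == ch & p$class == cl])
      if (length(pos) > 1) {
        dmin <- if (cl == "genic") 800 else 3000
        expect_true(all(diff(pos) >= dmin))
      }
    }
  }
  # probe validity re-verified independently
  for (i in seq_len(nrow(p))) {
    expect_equal(nchar(p$probe_seq[i]), 40L)
    expect_false(grepl("N", p$probe_seq[i]))
    expect_equal(probe_uniqueness(p$probe_seq[i], g), 1L)
    if (p$probe_strand[i] == "+") {
      expect_true(p$probe_end0[i] <= p$pos0[i] && p$pos0[i] < p$probe_end0[i] + 460)
    } else {
      expect_true(p$probe_start0[i] - 460 <= p$pos0[i] && p$pos0[i] < p$probe_start0[i])
    }
  }
  # determinism: identical inputs give byte-identical panel files
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  f1 <- write_panel(panel, d1)
  panel2 <- design_panel(sim$table, genes, g, d_genic = 800, d_intergenic = 3000)
  f2 <- write_panel(panel2, d2)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]))
  }
})
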