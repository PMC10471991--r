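#' Simulate a reference genome
#'
#' Sequences are i.i.d. uniform A/C/G/T. `repeat_spike` copies that many
#' randomly chosen 40-mers to a second location (on a chromosome chosen at
#' random), producing exact duplicates that exercise probe-design rescue;
#' the spiked source/destination positions are attached as attribute
#' `spikes`.
#'
#' @param chrom_lengths named chromosome lengths in bp (each >= 1000).
#' @param seed RNG seed (`set.seed` is called when non-NULL).
#' @param repeat_spike number of duplicated k-mers to plant.
#' @param spike_len length of the duplicated k-mers.
#' @return named `DNAStringSet`.
#' @export
simulate_reference <- function(chrom_lengths = c(chr1 = 1e5, chr2 = 1e5),
                               seed = NULL, repeat_spike = 0L, spike_len = 40L) {
  if (any(chrom_lengths < 1000)) stop_("chromosome lengths must be >= 1 kb")
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(
    chrom_lengths,
    function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1L)
  )
  spikes <- NULL
  if (repeat_spike > 0L) {
    spikes <- data.frame(
      src_chrom = character(), src_pos0 = integer(),
      dst_chrom = character(), dst_pos0 = integer(), stringsAsFactors = FALSE
    )
    for (k in seq_len(repeat_spike)) {
      src_ch <- sample(names(seqs), 1L)
      src <- sample.int(nchar(seqs[[src_ch]]) - spike_len, 1L)
      kmer <- substr(seqs[[src_ch]], src, src + spike_len - 1L)
      dst_ch <- sample(names(seqs), 1L)
      repeat {
        dst <- sample.int(nchar(seqs[[dst_ch]]) - spike_len, 1L)
        if (dst_ch != src_ch || abs(dst - src) >= spike_len) break
      }
      substr(seqs[[dst_ch]], dst, dst + spike_len - 1L) <- kmer
      spikes <- rbind(spikes, data.frame(
        src_chrom = src_ch, src_pos0 = src - 1L,
        dst_chrom = dst_ch, dst_pos0 = dst - 1L, stringsAsFactors = FALSE
      ))
    }
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(chrom_lengths)
  attr(genome, "spikes") <- spikes
  genome
}

#' Simulate non-overlapping gene models
#'
#' Places `floor(length * density)` genes per chromosome, each within its own
#' equal-width slot (so genes never overlap), with uniform random strand.
#'
#' @param genome named `DNAStringSet`.
#' @param density genes per bp (default 1 gene / 2 kb).
#' @param gene_length range of gene lengths, drawn uniformly.
#' @param seed RNG seed.
#' @return gene model data.frame (`gene_id`, `chrom`, `start0`, `end0`,
#'   `strand`).
#' @export
simulate_genes <- function(genome, density = 1 / 2000, gene_length = c(300L, 1200L),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chrom_lengths(genome)
  out <- list()
  gid <- 0L
  for (ch in names(lens)) {
    n <- floor(lens[[ch]] * density)
    if (n == 0L) next
    slot <- lens[[ch]] %/% n
    if (slot <= max(gene_length)) {
      stop_("gene density infeasible for chromosome %s (slot %d bp < max gene %d bp)",
            ch, slot, max(gene_length))
    }
    glen <- sample(gene_length[1L]:gene_length[2L], n, replace = TRUE)
    offset <- vapply(slot - glen, function(m) sample.int(m, 1L) - 1L, integer(1L))
    start0 <- (seq_len(n) - 1L) * slot + offset
    out[[ch]] <- data.frame(
      gene_id = sprintf("gene%04d", gid + seq_len(n)),
      chrom = ch, start0 = start0, end0 = start0 + glen,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    gid <- gid + n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write gene models to GFF3
#' @param genes gene model data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c(
    "##gff-version 3",
    sprintf(
      "%s\tspet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      genes$chrom, genes$start0 + 1L, genes$end0, genes$strand, genes$gene_id
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a structured multi-sample cohort
#'
#' Group allele frequencies follow the Balding-Nichols construction: an
#' ancestral frequency `p` is drawn per site, and each of `n_groups`
#' subpopulations draws `p_k ~ Beta(p (1 - F) / F, (1 - p) (1 - F) / F)`
#' for target differentiation `F`; genotypes are Hardy-Weinberg within
#' groups. Depths are negative-binomial (`mu = depth_mean`,
#' `size = depth_size`); genotypes are masked missing at `missing_rate`;
#' site QUAL and the INFO metrics QD/MQ/MQRankSum are drawn from pass/fail
#' mixtures (`fail_frac` of sites get one failing hard-filter metric) so the
#' filter cascade has work to do. REF is the reference base at each
#' simulated position; ALT is a transition with probability `ts_prob`.
#'
#' @param genome named `DNAStringSet`.
#' @param n_samples cohort size.
#' @param n_sites total number of biallelic sites (split across chromosomes
#'   in proportion to length).
#' @param n_groups number of subpopulations.
#' @param fst target differentiation in (0, 1); ignored when `n_groups = 1`.
#' @param maf_low lower bound of the ancestral allele-frequency draw
#'   (`p ~ U(maf_low, 1 - maf_low)`).
#' @param missing_rate genotype missingness rate.
#' @param depth_mean,depth_size negative-binomial depth model.
#' @param fail_frac fraction of sites given a failing INFO metric.
#' @param low_qual_frac fraction of sites given QUAL below 30.
#' @param ts_prob probability that the alt allele is a transition.
#' @param seed RNG seed.
#' @return list with `table` (a [variant_table()]), `groups` (factor named
#'   by sample) and `truth` (ancestral and per-group allele frequencies,
#'   target FST).
#' @export
simulate_cohort <- function(genome, n_samples = 160L, n_sites = 1000L,
                            n_groups = 2L, fst = 0.3, maf_low = 0.05,
                            missing_rate = 0.03, depth_mean = 80, depth_size = 2,
                            fail_frac = 0.05, low_qual_frac = 0.03,
                            ts_prob = 2 / 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_groups > 1L && (fst <= 0 || fst >= 1)) stop_("target FST must be in (0, 1)")
  lens <- chrom_lengths(genome)
  n_per <- setNames(pmax(1L, round(n_sites * lens / sum(lens))), names(lens))
  sites <- list()
  for (ch in names(lens)) {
    pos0 <- sort(sample.int(lens[[ch]], n_per[[ch]]) - 1L)
    ref <- strsplit(as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(pos0 + 1L, width = 1L)
    )), "")
    ref <- vapply(ref, `[`, character(1L), 1L)
    keep <- ref %in% c("A", "C", "G", "T")
    sites[[ch]] <- data.frame(chrom = ch, pos0 = pos0[keep], ref = ref[keep],
                              stringsAsFactors = FALSE)
  }
  s <- do.call(rbind, sites)
  ns <- nrow(s)
  s$alt <- draw_alt(s$ref, ts_prob)
  ## INFO / QUAL mixtures
  s$qual <- ifelse(runif(ns) < low_qual_frac, runif(ns, 5, 29.9), runif(ns, 50, 2000))
  s$QD <- runif(ns, 5, 35)
  s$MQ <- runif(ns, 45, 60)
  s$MQRankSum <- rnorm(ns, 0, 3)
  failing <- runif(ns) < fail_frac
  which_field <- sample(3L, ns, replace = TRUE)
  s$QD[failing & which_field == 1L] <- runif(sum(failing & which_field == 1L), 0, 1.9)
  s$MQ[failing & which_field == 2L] <- runif(sum(failing & which_field == 2L), 10, 39.9)
  s$MQRankSum[failing & which_field == 3L] <- runif(sum(failing & which_field == 3L), -30, -12.6)
  ## Balding-Nichols frequencies and HW genotypes within groups
  groups <- factor(sprintf("G%d", rep_len(seq_len(n_groups), n_samples)))
  groups <- sort(groups)
  p_anc <- runif(ns, maf_low, 1 - maf_low)
  p_grp <- matrix(p_anc, ns, n_groups)
  if (n_groups > 1L) {
    for (k in seq_len(n_groups)) {
      p_grp[, k] <- rbeta(ns, p_anc * (1 - fst) / fst, (1 - p_anc) * (1 - fst) / fst)
    }
  }
  gt <- matrix(NA_integer_, ns, n_samples)
  for (j in seq_len(n_samples)) {
    gt[, j] <- rbinom(ns, 2L, p_grp[, as.integer(groups[j])])
  }
  gt[matrix(runif(ns * n_samples) < missing_rate, ns, n_samples)] <- NA_integer_
  dp <- matrix(rnbinom(ns * n_samples, size = depth_size, mu = depth_mean), ns, n_samples)
  samples <- sprintf("S%03d", seq_len(n_samples))
  names(groups) <- samples
  tab <- variant_table(s, gt, dp, samples)
  list(
    table = tab,
    groups = groups,
    truth = list(p_ancestral = p_anc, p_group = p_grp, fst = if (n_groups > 1L) fst else NA_real_)
  )
}

draw_alt <- function(ref, ts_prob) {
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  tv_of <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  vapply(ref, function(b) {
    if (runif(1) < ts_prob) ts_of[[b]] else sample(tv_of[[b]], 1L)
  }, character(1L), USE.NAMES = FALSE)
}

#' Simulate a phenotype with a spiked causal marker
#'
#' `y = gamma * g_causal + group effect + N(0, noise_sd^2)`. The marker
#' effect `gamma` is either given directly or derived from a target fraction
#' of variance explained (`pve`): `gamma = sqrt(pve / (1 - pve) *
#' var_other / var(g))`. Missing causal genotypes are mean-imputed for
#' phenotype generation only. With `ordinal_levels` the continuous phenotype
#' is discretized into those levels by quantile bins (emulating ordinal
#' trait scores).
#'
#' @param x a `variant_table`.
#' @param causal_site site index of the causal marker.
#' @param effect marker effect `gamma` (exclusive with `pve`).
#' @param pve target fraction of phenotypic variance explained by the
#'   marker.
#' @param groups optional factor of group labels for group effects.
#' @param group_effect_sd standard deviation of per-group intercepts.
#' @param noise_sd residual standard deviation.
#' @param ordinal_levels optional numeric levels for ordinal discretization.
#' @param seed RNG seed.
#' @return list with `phenotype` (named numeric), `effect`, `realized_pve`
#'   and `causal_site`.
#' @export
simulate_phenotype <- function(x, causal_site, effect = NULL, pve = NULL,
                               groups = NULL, group_effect_sd = 0,
                               noise_sd = 1, ordinal_levels = NULL, seed = NULL) {
  stopifnot(inherits(x, "variant_table"))
  if (!is.null(seed)) set.seed(seed)
  if (causal_site < 1 || causal_site > n_sites(x)) stop_("causal site not in table")
  if (is.null(effect) == is.null(pve)) stop_("give exactly one of effect or pve")
  g <- as.numeric(x$gt[causal_site, ])
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  u <- rep(0, n_samples(x))
  if (!is.null(groups) && group_effect_sd > 0) {
    groups <- as.factor(groups)
    u <- rnorm(nlevels(groups), 0, group_effect_sd)[as.integer(groups)]
  }
  var_other <- noise_sd^2 + var(u)
  if (is.null(effect)) {
    if (pve <= 0 || pve >= 1) stop_("pve must be in (0, 1)")
    if (var(g) == 0) stop_("causal site is monomorphic")
    effect <- sqrt(pve / (1 - pve) * var_other / var(g))
  }
  y <- effect * g + u + rnorm(n_samples(x), 0, noise_sd)
  realized_pve <- var(effect * g) / var(y)
  if (!is.null(ordinal_levels)) {
    br <- quantile(y, probs = seq(0, 1, length.out = length(ordinal_levels) + 1L))
    br[1L] <- -Inf
    br[length(br)] <- Inf
    y <- ordinal_levels[as.integer(cut(y, br, labels = FALSE, include.lowest = TRUE))]
  }
  list(
    phenotype = setNames(y, x$samples),
    effect = effect, realized_pve = realized_pve, causal_site = causal_site
  )
}

#' Write group labels / phenotypes to TSV
#' @param x named vector (groups or phenotype values).
#' @param path output file.
#' @param value_col name of the value column.
#' @return `path`, invisibly.
#' @export
write_sample_tsv <- function(x, path, value_col = "value") {
  d <- data.frame(sample = names(x), value = as.vector(x), stringsAsFactors = FALSE)
  names(d)[2L] <- value_col
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample TSV back into a named vector
#' @param path TSV with a `sample` column plus one value column.
#' @return named vector.
#' @export
read_sample_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  setNames(d[[2L]], d$sample)
}

#' Simulate a complete SPET input set and optionally write it to disk
#'
#' Convenience wrapper producing every file the toolkit consumes: reference
#' FASTA, gene GFF3, cohort VCF (GT:DP with QD/MQ/MQRankSum INFO), group
#' labels TSV, phenotype TSV and a truth JSON (target FST, causal site,
#' realized PVE).
#'
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed RNG seed driving all generators.
#' @param chrom_lengths,repeat_spike passed to [simulate_reference()].
#' @param gene_density passed to [simulate_genes()].
#' @param causal_pve target PVE of the spiked causal marker.
#' @param ... passed to [simulate_cohort()].
#' @return list with `genome`, `genes`, `cohort` (table/groups/truth),
#'   `phenotype`, and `files` (named paths when written).
#' @export
simulate_dataset <- function(out_dir = NULL, seed = 1L,
                             chrom_lengths = c(chr1 = 1e5, chr2 = 1e5),
                             repeat_spike = 0L, gene_density = 1 / 2000,
                             causal_pve = 0.45, ...) {
  set.seed(seed)
  genome <- simulate_reference(chrom_lengths, repeat_spike = repeat_spike)
  genes <- simulate_genes(genome, density = gene_density)
  cohort <- simulate_cohort(genome, ...)
  ## causal marker: common, but minimally differentiated between groups so the
  ## spiked trait is not confounded with the structure covariates
  maf <- site_maf(cohort$table)
  eligible <- which(!is.na(maf) & maf >= 0.2)
  if (!length(eligible)) eligible <- which.max(maf)
  pg <- cohort$truth$p_group
  causal <- if (ncol(pg) > 1L) {
    spread <- apply(pg, 1L, function(r) diff(range(r)))
    eligible[which.min(spread[eligible])]
  } else {
    eligible[which.max(maf[eligible])]
  }
  pheno <- simulate_phenotype(cohort$table, causal, pve = causal_pve,
                              groups = cohort$groups)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      fasta = file.path(out_dir, "reference.fasta"),
      gff = file.path(out_dir, "genes.gff3"),
      vcf = file.path(out_dir, "cohort.vcf"),
      groups = file.path(out_dir, "groups.tsv"),
      pheno = file.path(out_dir, "phenotype.tsv"),
      truth = file.path(out_dir, "truth.json")
    )
    write_fasta(genome, files[["fasta"]])
    write_gff3(genes, files[["gff"]])
    write_vcf(cohort$table, files[["vcf"]], contig_lengths = chrom_lengths(genome))
    write_sample_tsv(cohort$groups, files[["groups"]], "group")
    write_sample_tsv(pheno$phenotype, files[["pheno"]], "phenotype")
    jsonlite::write_json(
      list(
        seed = seed, target_fst = cohort$truth$fst,
        causal_site = causal,
        causal_chrom = cohort$table$sites$chrom[causal],
        causal_pos0 = cohort$table$sites$pos0[causal],
        effect = pheno$effect, realized_pve = pheno$realized_pve
      ),
      files[["truth"]], auto_unbox = TRUE, digits = NA
    )
  }
  list(genome = genome, genes = genes, cohort = cohort, phenotype = pheno, files = files)
}
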