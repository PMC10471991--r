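#' Per-site allele frequencies, expected heterozygosity and PIC
#'
#' For a biallelic site with alt-allele frequency `p` (over called genotypes)
#' and `q = 1 - p`, the expected heterozygosity under Hardy-Weinberg
#' equilibrium is `H = 1 - p^2 - q^2` and the polymorphic information content
#' is `PIC = H - 2 p^2 q^2`. Both are maximal at `p = 0.5` (H = 0.5,
#' PIC = 0.375). Sites with no called genotypes get `NA` statistics.
#'
#' @param x a `variant_table`.
#' @return data.frame with columns `chrom`, `pos0`, `n_called`, `p`, `q`,
#'   `maf`, `H`, `PIC`.
#' @export
site_stats <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  n_called <- site_called(x)
  p <- ifelse(n_called > 0, site_alt_count(x) / (2 * n_called), NA_real_)
  q <- 1 - p
  H <- het_expected(p)
  data.frame(
    chrom = x$sites$chrom, pos0 = x$sites$pos0, n_called = n_called,
    p = p, q = q, maf = pmin(p, q),
    H = H, PIC = pic(p),
    stringsAsFactors = FALSE
  )
}

#' Expected heterozygosity and PIC as functions of allele frequency
#'
#' `het_expected(p) = 1 - p^2 - (1-p)^2`; `pic(p) = het_expected(p) -
#' 2 p^2 (1-p)^2`. Vectorized over `p`.
#'
#' @param p allele frequency in `[0, 1]`.
#' @return numeric vector.
#' @export
het_expected <- function(p) 1 - p^2 - (1 - p)^2

#' @rdname het_expected
#' @export
pic <- function(p) het_expected(p) - 2 * p^2 * (1 - p)^2

#' Windowed nucleotide diversity
#'
#' Per-site diversity is the unbiased pairwise heterozygosity
#' `pi_s = 2 j (c - j) / (c (c - 1))` with `j` the alt allele count and `c`
#' the number of called alleles; sites with `c < 2` are skipped. Each
#' non-overlapping window of `window` bp gets
#' `pi = sum(pi_s over sites in window) / window` (per-bp diversity, the
#' VCFtools windowed-pi convention).
#'
#' @param x a `variant_table`.
#' @param window window size in bp.
#' @param chrom_lengths optional named lengths; windows then tile each whole
#'   chromosome, otherwise they stop at the last variant.
#' @return data.frame with `chrom`, `start0`, `end0`, `n_sites`, `pi`.
#' @export
windowed_pi <- function(x, window = 1000L, chrom_lengths = NULL) {
  stopifnot(inherits(x, "variant_table"), window >= 1)
  ps <- site_pi(x)
  out <- list()
  for (ch in unique(x$sites$chrom)) {
    in_ch <- x$sites$chrom == ch
    pos <- x$sites$pos0[in_ch]
    v <- ps[in_ch]
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(pos) + 1L
    starts <- seq(0L, len - 1L, by = window)
    idx <- findInterval(pos, starts)
    pi_sum <- vapply(
      seq_along(starts),
      function(w) sum(v[idx == w], na.rm = TRUE),
      numeric(1L)
    )
    n_in <- vapply(seq_along(starts), function(w) sum(idx == w & !is.na(v)), integer(1L))
    out[[ch]] <- data.frame(
      chrom = ch, start0 = starts,
      end0 = pmin(starts + window, len),
      n_sites = n_in, pi = pi_sum / window,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## per-site unbiased pairwise diversity; NA where fewer than 2 called alleles
site_pi <- function(x) {
  c_al <- 2 * site_called(x)
  j <- site_alt_count(x)
  ifelse(c_al >= 2, 2 * j * (c_al - j) / (c_al * (c_al - 1)), NA_real_)
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T. Records whose ref or alt is not a single
#' base are skipped (count reported). With zero transversions the ratio is
#' `NA` (flagged `undefined`).
#'
#' @param x a `variant_table` (or data.frame with `ref`, `alt`).
#' @return list with `ratio`, `n_ts`, `n_tv`, `n_skipped`, `undefined`.
#' @export
tstv <- function(x) {
  s <- if (inherits(x, "variant_table")) x$sites else x
  snp <- nchar(s$ref) == 1L & nchar(s$alt) == 1L &
    s$ref %in% c("A", "C", "G", "T") & s$alt %in% c("A", "C", "G", "T") &
    s$ref != s$alt
  pair <- paste0(s$ref[snp], s$alt[snp])
  is_ts <- pair %in% c("AG", "GA", "CT", "TC")
  n_ts <- sum(is_ts)
  n_tv <- sum(!is_ts)
  list(
    ratio = if (n_tv == 0) NA_real_ else n_ts / n_tv,
    n_ts = n_ts, n_tv = n_tv, n_skipped = sum(!snp),
    undefined = n_tv == 0
  )
}

#' Per-sample heterozygosity (percent)
#'
#' `100 * (het calls) / (called sites)` per sample; samples with zero called
#' sites get `NA`.
#'
#' @param x a `variant_table`.
#' @return named numeric vector (percent).
#' @export
sample_heterozygosity <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  called <- colSums(!is.na(x$gt))
  het <- colSums(x$gt == 1L, na.rm = TRUE)
  setNames(ifelse(called > 0, 100 * het / called, NA_real_), x$samples)
}

#' SNP spacing summary per chromosome
#'
#' The per-chromosome mean interdistance is `chromosome length / number of
#' SNPs`; the cross-chromosome mean is the unweighted mean of the per-
#' chromosome means. The maximum successive gap is reported where positions
#' are available. Chromosomes with zero SNPs are excluded with a warning.
#'
#' @param x a `variant_table`, a named list of sorted positions per
#'   chromosome, or a named numeric vector of SNP counts per chromosome (no
#'   gap statistics in the latter case).
#' @param chrom_lengths named chromosome lengths (bp).
#' @return data.frame (`chrom`, `chrom_length`, `n_snps`, `mean_spacing_bp`,
#'   `max_gap_bp`) with attribute `cross_chrom_mean_bp`.
#' @export
snp_spacing_summary <- function(x, chrom_lengths) {
  if (inherits(x, "variant_table")) {
    x <- split(x$sites$pos0, x$sites$chrom)[unique(x$sites$chrom)]
  }
  if (is.numeric(x) && !is.list(x)) {
    counts <- x
    pos_list <- setNames(vector("list", length(counts)), names(counts))
  } else {
    pos_list <- x
    counts <- vapply(pos_list, length, numeric(1L))
  }
  empty <- counts == 0
  if (any(empty)) {
    warn_("chromosome(s) with 0 SNPs excluded: %s", paste(names(counts)[empty], collapse = ", "))
    counts <- counts[!empty]
    pos_list <- pos_list[!empty]
  }
  unknown <- setdiff(names(counts), names(chrom_lengths))
  if (length(unknown)) stop_("no length for chromosome(s): %s", paste(unknown, collapse = ", "))
  lens <- unname(chrom_lengths[names(counts)])
  max_gap <- vapply(seq_along(counts), function(i) {
    pos <- pos_list[[i]]
    if (is.null(pos) || length(pos) < 2L) NA_real_ else max(diff(sort(pos)))
  }, numeric(1L))
  out <- data.frame(
    chrom = names(counts), chrom_length = lens, n_snps = as.integer(counts),
    mean_spacing_bp = lens / counts, max_gap_bp = max_gap,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "cross_chrom_mean_bp") <- mean(out$mean_spacing_bp)
  out
}

#' Pairwise FST between labeled groups
#'
#' Default estimator is Hudson's, computed per site with the finite-sample
#' correction of the between-group frequency difference and combined across
#' sites as a ratio of averages; sites where the numerator and denominator
#' are undefined (both groups monomorphic for the same allele, or a group
#' with fewer than 2 called alleles) are skipped. A Weir-Cockerham estimator
#' is available via `estimator = "wc"`.
#'
#' @param x a `variant_table`.
#' @param groups group labels per sample (named by sample id, or in sample
#'   order).
#' @param estimator `"hudson"` (default) or `"wc"`.
#' @return list of class `fst_matrix`: `fst` (symmetric matrix, diagonal 0),
#'   `groups` (levels), `estimator`.
#' @export
pairwise_fst <- function(x, groups, estimator = c("hudson", "wc")) {
  stopifnot(inherits(x, "variant_table"))
  estimator <- match.arg(estimator)
  groups <- align_groups(x, groups)
  lv <- levels(groups)
  if (length(lv) < 2L) stop_("need at least 2 groups")
  m <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (a in seq_along(lv)) {
    for (b in seq_along(lv)) {
      if (b <= a) next
    ga <- x$gt[, groups == lv[a], drop = FALSE]
    gb <- x$gt[, groups == lv[b], drop = FALSE]
    f <- if (estimator == "hudson") fst_hudson(ga, gb) else fst_wc(ga, gb)
      m[a, b] <- m[b, a] <- f
    }
  }
  structure(list(fst = m, groups = lv, estimator = estimator), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("pairwise FST (%s estimator):\n", x$estimator))
  print(round(x$fst, 4))
  invisible(x)
}

align_groups <- function(x, groups) {
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(x$samples, names(groups))
    if (length(missing_ids)) stop_("no group label for sample(s): %s", paste(missing_ids, collapse = ", "))
    groups <- groups[x$samples]
  } else if (length(groups) != n_samples(x)) {
    stop_("groups length (%d) differs from cohort size (%d)", length(groups), n_samples(x))
  }
  droplevels(as.factor(groups))
}

group_freq <- function(g) {
  called <- rowSums(!is.na(g))
  n_al <- 2 * called
  p <- ifelse(n_al > 0, rowSums(g, na.rm = TRUE) / n_al, NA_real_)
  list(p = p, n = n_al)
}

## Hudson estimator with finite-sample correction, ratio of averages
fst_hudson <- function(ga, gb) {
  fa <- group_freq(ga)
  fb <- group_freq(gb)
  ok <- !is.na(fa$p) & !is.na(fb$p) & fa$n >= 2 & fb$n >= 2
  p1 <- fa$p[ok]; p2 <- fb$p[ok]
  n1 <- fa$n[ok]; n2 <- fb$n[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  if (!any(keep)) stop_("no informative sites for FST (all monomorphic)")
  sum(num[keep]) / sum(den[keep])
}

## Weir & Cockerham theta for two groups, diploid, ratio of averages
fst_wc <- function(ga, gb) {
  freq_het <- function(g) {
    called <- rowSums(!is.na(g))
    p <- ifelse(called > 0, rowSums(g, na.rm = TRUE) / (2 * called), NA_real_)
    h <- ifelse(called > 0, rowSums(g == 1L, na.rm = TRUE) / called, NA_real_)
    list(p = p, h = h, n = called)
  }
  A <- freq_het(ga)
  B <- freq_het(gb)
  ok <- !is.na(A$p) & !is.na(B$p) & A$n >= 2 & B$n >= 2
  r <- 2
  n1 <- A$n[ok]; n2 <- B$n[ok]
  p1 <- A$p[ok]; p2 <- B$p[ok]
  h1 <- A$h[ok]; h2 <- B$h[ok]
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  keep <- (a + b + cc) != 0 & is.finite(a + b + cc)
  if (!any(keep)) stop_("no informative sites for FST (all monomorphic)")
  sum(a[keep]) / sum(a[keep] + b[keep] + cc[keep])
}

#' Identity-by-state kinship matrix
#'
#' `K[i, j]` is the mean over mutually called sites of
#' `(2 - |g_i - g_j|) / 2`; identical genotype vectors give 1, opposite
#' homozygotes 0. Pairs with no shared called site get `NA`.
#'
#' @param x a `variant_table` with at least 2 samples.
#' @return list of class `kinship_matrix` with the symmetric `K`.
#' @export
ibs_kinship <- function(x) {
  stopifnot(inherits(x, "variant_table"))
  n <- n_samples(x)
  if (n < 2L) stop_("need at least 2 samples")
  K <- matrix(NA_real_, n, n, dimnames = list(x$samples, x$samples))
  g <- x$gt
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      K[i, j] <- K[j, i] <- if (any(ok)) mean((2 - abs(g[ok, i] - g[ok, j])) / 2) else NA_real_
    }
  }
  diag(K) <- 1
  structure(list(K = K, samples = x$samples), class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("IBS kinship over %d samples; mean off-diagonal %.3f\n",
              nrow(x$K), mean(x$K[upper.tri(x$K)], na.rm = TRUE)))
  invisible(x)
}

#' Principal component analysis of the genotype matrix
#'
#' Genotypes are mean-centered per site with missing values replaced by the
#' site mean (hence centered to 0); the sample covariance is
#' eigendecomposed. Scores and the fraction of variance explained are
#' returned in decreasing eigenvalue order.
#'
#' @param x a `variant_table`.
#' @param n_components number of components, at most
#'   `min(n_samples - 1, n_sites)`.
#' @return list of class `genotype_pca`: `scores` (samples x components),
#'   `explained` (fractions), `sdev`.
#' @export
genotype_pca <- function(x, n_components = 2L) {
  stopifnot(inherits(x, "variant_table"))
  maxc <- min(n_samples(x) - 1L, n_sites(x))
  if (n_components > maxc) stop_("n_components (%d) exceeds %d", n_components, maxc)
  g <- t(x$gt) # samples x sites
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  g <- sweep(g, 2L, mu)
  if (all(abs(g) < 1e-12)) stop_("no variance in genotype matrix")
  pr <- prcomp(g, center = FALSE)
  total_var <- sum(pr$sdev^2)
  structure(list(
    scores = pr$x[, seq_len(n_components), drop = FALSE],
    explained = (pr$sdev^2 / total_var)[seq_len(n_components)],
    sdev = pr$sdev
  ), class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf(
    "genotype PCA: %d components, explaining %s%% of variance\n",
    ncol(x$scores), paste(round(100 * x$explained, 1), collapse = " + ")
  ))
  invisible(x)
}

#' @export
plot.genotype_pca <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1L else as.integer(as.factor(groups))
  graphics::plot(
    x$scores[, 1L], x$scores[, 2L], col = col, pch = 19,
    xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1L]),
    ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2L]), ...
  )
  invisible(x)
}
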