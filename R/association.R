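#' Bonferroni genome-wide significance threshold
#'
#' With `m` tested markers and family-wise level `alpha`, the per-marker
#' threshold is `alpha / m`; its negative decadic logarithm is the usual
#' Manhattan-plot cutoff.
#'
#' @param m number of tests (markers), `>= 1`.
#' @param alpha genome-wide type-I error level.
#' @return list of class `significance_threshold`: `alpha`, `m`,
#'   `p_threshold`, `neg_log10`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1L || is.na(m) || m < 1) stop_("m must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop_("alpha must be in (0, 1)")
  structure(
    list(alpha = alpha, m = as.integer(m), p_threshold = alpha / m,
         neg_log10 = -log10(alpha / m)),
    class = "significance_threshold"
  )
}

#' @export
print.significance_threshold <- function(x, ...) {
  cat(sprintf(
    "Bonferroni threshold: alpha = %g over m = %d tests -> p < %.4g (-log10 = %.3f)\n",
    x$alpha, x$m, x$p_threshold, x$neg_log10
  ))
  invisible(x)
}

#' Single-marker GLM association scan
#'
#' Fits, per site, the least-squares model
#' `y = mu + covariates %*% beta + g * gamma` with `g` the minor-allele
#' dosage, and tests `gamma = 0` (two-sided t test). PVE is the incremental
#' R-squared of the marker term over the covariate-only model on the same
#' samples. Samples missing the genotype, phenotype or a covariate are
#' dropped per site; sites with fewer than `min_classes` distinct genotype
#' values after the drop are skipped (`NA` row). Effects are reported for
#' the minor allele: at sites where the alt allele is the major one the
#' dosage is flipped to `2 - g` before fitting.
#'
#' @param x a `variant_table`.
#' @param phenotype numeric phenotype, named by sample id or in sample order.
#' @param covariates optional numeric matrix of structure covariates (e.g.
#'   leading PCs from [genotype_pca()]), rows aligned with samples.
#' @param alpha genome-wide level for the Bonferroni call.
#' @param min_classes minimum number of distinct genotype values required to
#'   test a site.
#' @return data.frame of class `spet_scan` with columns `chrom`, `pos0`,
#'   `maf`, `n`, `effect`, `se`, `p_value`, `pve`, `significant`; the
#'   [bonferroni_threshold()] used (m = number of tested sites) is attached
#'   as attribute `threshold`.
#' @export
glm_scan <- function(x, phenotype, covariates = NULL, alpha = 0.05,
                     min_classes = 3L) {
  stopifnot(inherits(x, "variant_table"))
  y <- align_phenotype(x, phenotype)
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n_samples(x)) stop_("covariates rows (%d) differ from cohort size (%d)", nrow(C), n_samples(x))
    if (qr(cbind(1, C))$rank < ncol(C) + 1L) stop_("rank-deficient covariate matrix")
  }
  ns <- n_sites(x)
  eff <- se <- pv <- pve <- maf <- rep(NA_real_, ns)
  nn <- rep(NA_integer_, ns)
  for (i in seq_len(ns)) {
    g <- as.numeric(x$gt[i, ])
    ok <- !is.na(g) & !is.na(y)
    if (!is.null(C)) ok <- ok & complete.cases(C)
    g_ok <- g[ok]
    if (length(unique(g_ok)) < min_classes) next
    p_alt <- mean(g_ok) / 2
    if (p_alt > 0.5) g_ok <- 2 - g_ok # minor-allele orientation
    fit <- marker_ols(y[ok], if (is.null(C)) NULL else C[ok, , drop = FALSE], g_ok)
    if (is.null(fit)) next
    eff[i] <- fit$effect
    se[i] <- fit$se
    pv[i] <- fit$p
    pve[i] <- fit$pve
    maf[i] <- min(p_alt, 1 - p_alt)
    nn[i] <- sum(ok)
  }
  m <- sum(!is.na(pv))
  if (m == 0L) stop_("no testable sites")
  thr <- bonferroni_threshold(m, alpha)
  out <- data.frame(
    chrom = x$sites$chrom, pos0 = x$sites$pos0,
    maf = maf, n = nn, effect = eff, se = se, p_value = pv, pve = pve,
    significant = !is.na(pv) & pv < thr$p_threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- thr
  class(out) <- c("spet_scan", "data.frame")
  out
}

## OLS of y on [1, C, g]; returns marker effect, se, two-sided p, and
## incremental R^2 of the marker over the covariate-only model
marker_ols <- function(y, C, g) {
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), C)
  X <- cbind(X0, marker = g)
  n <- length(y)
  k <- ncol(X)
  if (n <= k) return(NULL)
  XtX <- crossprod(X)
  XtXi <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(XtXi)) return(NULL)
  beta <- XtXi %*% crossprod(X, y)
  res <- y - X %*% beta
  rss1 <- sum(res^2)
  df <- n - k
  sigma2 <- rss1 / df
  se_g <- sqrt(sigma2 * XtXi[k, k])
  tval <- beta[k] / se_g
  ## covariate-only fit on the same samples
  q0 <- qr(X0)
  rss0 <- sum(qr.resid(q0, y)^2)
  tss <- sum((y - mean(y))^2)
  list(
    effect = unname(beta[k]),
    se = se_g,
    p = 2 * pt(-abs(tval), df),
    pve = if (tss > 0) max(0, (rss0 - rss1) / tss) else NA_real_
  )
}

align_phenotype <- function(x, phenotype) {
  if (!is.null(names(phenotype))) {
    missing_ids <- setdiff(x$samples, names(phenotype))
    if (length(missing_ids)) stop_("no phenotype for sample(s): %s", paste(missing_ids, collapse = ", "))
    phenotype <- phenotype[x$samples]
  } else if (length(phenotype) != n_samples(x)) {
    stop_("phenotype length (%d) differs from cohort size (%d)", length(phenotype), n_samples(x))
  }
  as.numeric(phenotype)
}

#' @export
print.spet_scan <- function(x, ...) {
  thr <- attr(x, "threshold")
  cat(sprintf(
    "GLM association scan: %d sites (%d tested), %d significant at p < %.3g (-log10 = %.3f)\n",
    nrow(x), thr$m, sum(x$significant), thr$p_threshold, thr$neg_log10
  ))
  invisible(x)
}

#' @export
summary.spet_scan <- function(object, ...) {
  hits <- object[object$significant, , drop = FALSE]
  hits <- hits[order(hits$p_value), , drop = FALSE]
  print(object)
  if (nrow(hits)) {
    cat("top hits:\n")
    print(head(hits, 10L), row.names = FALSE)
  }
  invisible(hits)
}

#' Basic Manhattan plot of a scan
#' @param x a `spet_scan`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spet_scan <- function(x, ...) {
  thr <- attr(x, "threshold")
  chrom <- chrom_order(x$chrom)
  offset <- c(0, cumsum(tapply(x$pos0, chrom, max, na.rm = TRUE)))
  gx <- x$pos0 + offset[as.integer(chrom)]
  graphics::plot(
    gx, -log10(x$p_value), col = as.integer(chrom) %% 2 + 1L, pch = 20,
    xlab = "genome position", ylab = expression(-log[10](p)), ...
  )
  graphics::abline(h = thr$neg_log10, lty = 2)
  invisible(x)
}

#' Nearest gene for association hits
#'
#' Distance is 0 when the position falls inside a gene body; otherwise the
#' signed distance in bp to the nearest gene boundary (positive downstream
#' of the gene end, negative upstream of the gene start), nearest by
#' absolute distance with ties broken toward the smaller `gene_id`.
#'
#' @param chrom,pos0 hit location(s), vectorized (0-based position).
#' @param genes gene models (see [read_gff_genes()]).
#' @return data.frame with `chrom`, `pos0`, `gene_id`, `distance_bp`
#'   (`NA` for chromosomes without genes).
#' @export
nearest_gene <- function(chrom, pos0, genes) {
  stopifnot(length(chrom) == length(pos0))
  out <- data.frame(
    chrom = as.character(chrom), pos0 = as.integer(pos0),
    gene_id = NA_character_, distance_bp = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(chrom)) {
    g <- genes[genes$chrom == chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- numeric(nrow(g))
    inside <- pos0[i] >= g$start0 & pos0[i] < g$end0
    after <- pos0[i] >= g$end0
    before <- pos0[i] < g$start0
    d[inside] <- 0
    d[after] <- pos0[i] - g$end0[after] + 1
    d[before] <- -(g$start0[before] - pos0[i])
    ord <- order(abs(d), g$gene_id)
    out$gene_id[i] <- g$gene_id[ord[1L]]
    out$distance_bp[i] <- d[ord[1L]]
  }
  out
}

#' Annotate significant scan hits with their nearest gene
#' @param scan a `spet_scan`.
#' @param genes gene models.
#' @return the significant rows of `scan` with `gene_id` and `distance_bp`
#'   columns, ordered by p-value.
#' @export
annotate_hits <- function(scan, genes) {
  scan <- as.data.frame(scan)
  hits <- scan[scan$significant & !is.na(scan$p_value), , drop = FALSE]
  if (!nrow(hits)) return(cbind(hits, gene_id = character(0), distance_bp = numeric(0)))
  ng <- nearest_gene(hits$chrom, hits$pos0, genes)
  hits$gene_id <- ng$gene_id
  hits$distance_bp <- ng$distance_bp
  hits[order(hits$p_value), , drop = FALSE]
}
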