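#' Construct a variant table
#'
#' The central genotype container: per-site records plus an alt-allele dosage
#' matrix and an optional read-depth matrix. Genotypes are coded 0 (hom ref),
#' 1 (het), 2 (hom alt) and `NA` (missing). Positions are 0-based (`pos0`);
#' sites are kept sorted by chromosome (order of appearance) then position.
#'
#' @param sites data.frame with at least `chrom`, `pos0`, `ref`, `alt`;
#'   optionally `qual` and numeric INFO columns such as `QD`, `MQ`,
#'   `MQRankSum` used by [apply_hard_filter()].
#' @param gt integer matrix, `nrow(sites)` x `n_samples`, values in
#'   `c(0, 1, 2, NA)`.
#' @param dp optional non-negative integer depth matrix with the same
#'   dimensions as `gt`, or `NULL` when depth is unknown.
#' @param samples character vector of sample identifiers (columns of `gt`).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, dp = NULL, samples = colnames(gt)) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "pos0", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop_("sites is missing columns: %s", paste(miss, collapse = ", "))
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites)) stop_("gt has %d rows but sites has %d", nrow(gt), nrow(sites))
  if (!all(gt %in% c(0L, 1L, 2L, NA))) stop_("gt values must be 0, 1, 2 or NA")
  storage.mode(gt) <- "integer"
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    if (!identical(dim(dp), dim(gt))) stop_("dp dimensions differ from gt")
    if (any(dp < 0, na.rm = TRUE)) stop_("negative depths")
    storage.mode(dp) <- "integer"
  }
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(gt)))
  if (length(samples) != ncol(gt)) stop_("samples length differs from ncol(gt)")
  colnames(gt) <- samples
  if (!is.null(dp)) colnames(dp) <- samples
  sites$chrom <- as.character(sites$chrom)
  ord <- order(chrom_order(sites$chrom), sites$pos0)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  gt <- gt[ord, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
  structure(
    list(sites = sites, gt = gt, dp = dp, samples = samples),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(
    "variant_table: %d sites x %d samples (%s depth)\n",
    n_sites(x), n_samples(x), if (is.null(x$dp)) "no" else "with"
  ))
  cat(sprintf("  chromosomes: %s\n", paste(unique(x$sites$chrom), collapse = ", ")))
  cat(sprintf("  missing genotype fraction: %.3f\n", mean(is.na(x$gt))))
  invisible(x)
}

#' Number of sites / samples in a variant table
#' @param x a `variant_table`
#' @return integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a variant table by site index
#'
#' @param x a `variant_table`
#' @param i site index (logical or integer, recycled by the usual rules)
#' @param ... ignored
#' @return a `variant_table` with the selected sites.
#' @export
`[.variant_table` <- function(x, i, ...) {
  variant_table(
    x$sites[i, , drop = FALSE],
    x$gt[i, , drop = FALSE],
    if (!is.null(x$dp)) x$dp[i, , drop = FALSE] else NULL,
    x$samples
  )
}

## Per-site helpers shared by filtering and statistics -----------------------

site_called <- function(x) rowSums(!is.na(x$gt))

site_alt_count <- function(x) rowSums(x$gt, na.rm = TRUE)

## minor allele count over called genotypes (het adds 1, hom-alt adds 2)
site_mac <- function(x) {
  ac <- site_alt_count(x)
  an <- 2L * site_called(x)
  pmin(ac, an - ac)
}

site_maf <- function(x) {
  an <- 2 * site_called(x)
  p <- ifelse(an > 0, site_alt_count(x) / an, NA_real_)
  pmin(p, 1 - p)
}

site_missing_frac <- function(x) rowMeans(is.na(x$gt))
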