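#' Filter cascade configuration
#'
#' Bundles the thresholds of the post-calling filter cascade. Defaults follow
#' the standard GATK-style hard filter plus the cohort-level depth-support
#' and site filters used for SPET genotype matrices.
#'
#' @param hard_filter OR-list expression over INFO fields, e.g.
#'   `"QD<2.0||MQ<40.0||MQRankSum<-12.5"`.
#' @param min_dp_genotype genotypes with depth strictly below this are masked
#'   missing.
#' @param support_dp,support_min_samples keep a site only if at least
#'   `support_min_samples` samples (an absolute count, or a fraction of the
#'   cohort when < 1) have depth strictly above `support_dp`.
#' @param min_mac minimum minor allele count.
#' @param max_missing_frac maximum fraction of missing genotypes per site.
#' @param min_site_q minimum site QUAL.
#' @param min_maf minimum minor allele frequency over called genotypes.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(hard_filter = "QD<2.0||MQ<40.0||MQRankSum<-12.5",
                          min_dp_genotype = 5L,
                          support_dp = 10L,
                          support_min_samples = 96L,
                          min_mac = 3L,
                          max_missing_frac = 0.5,
                          min_site_q = 30,
                          min_maf = 0.05) {
  stopifnot(
    min_dp_genotype >= 0, support_dp >= 0, support_min_samples >= 0,
    min_mac >= 0, max_missing_frac >= 0, max_missing_frac <= 1,
    min_site_q >= 0, min_maf >= 0, min_maf <= 0.5
  )
  structure(
    list(
      hard_filter = hard_filter, min_dp_genotype = min_dp_genotype,
      support_dp = support_dp, support_min_samples = support_min_samples,
      min_mac = min_mac, max_missing_frac = max_missing_frac,
      min_site_q = min_site_q, min_maf = min_maf
    ),
    class = "filter_config"
  )
}

## parse "FIELD OP NUMBER || ..." into a clause table; errors before any
## evaluation so a bad expression never half-applies
parse_hard_filter <- function(expr) {
  if (!is_string(expr) || !nzchar(trimws(expr))) stop_("unparsable hard-filter expression")
  clauses <- trimws(strsplit(expr, "||", fixed = TRUE)[[1L]])
  rx <- "^([A-Za-z_][A-Za-z0-9_]*)\\s*(<=|>=|<|>)\\s*([-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?)$"
  ok <- grepl(rx, clauses)
  if (!all(ok)) stop_("unparsable hard-filter clause: '%s'", clauses[!ok][1L])
  data.frame(
    field = sub(rx, "\\1", clauses),
    op = sub(rx, "\\2", clauses),
    value = as.numeric(sub(rx, "\\3", clauses)),
    stringsAsFactors = FALSE
  )
}

#' Apply a hard-filter expression to site INFO metrics
#'
#' A site fails when any clause whose field is present (non-missing) at that
#' site evaluates true; clauses with a missing field are skipped, so a site
#' is never failed for lacking an annotation.
#'
#' @param x a `variant_table` whose `sites` carry the INFO columns named in
#'   the expression.
#' @param expr OR-list of `FIELD OP NUMBER` clauses, `OP` one of
#'   `<, <=, >, >=`.
#' @return logical vector, `TRUE` where the site passes.
#' @export
apply_hard_filter <- function(x, expr) {
  stopifnot(inherits(x, "variant_table"))
  cl <- parse_hard_filter(expr)
  fail <- rep(FALSE, n_sites(x))
  for (i in seq_len(nrow(cl))) {
    v <- x$sites[[cl$field[i]]]
    if (is.null(v)) next
    hit <- switch(cl$op[i],
      "<" = v < cl$value[i],
      "<=" = v <= cl$value[i],
      ">" = v > cl$value[i],
      ">=" = v >= cl$value[i]
    )
    fail <- fail | (!is.na(hit) & hit)
  }
  !fail
}

#' Mask low-depth genotypes as missing
#'
#' Genotypes backed by strictly fewer than `min_dp` reads are set missing;
#' depths are left unchanged. Tables without depth information are returned
#' untouched.
#'
#' @param x a `variant_table`.
#' @param min_dp minimum read depth for a genotype call.
#' @return the masked `variant_table`.
#' @export
mask_low_depth <- function(x, min_dp = 5L) {
  stopifnot(inherits(x, "variant_table"))
  if (is.null(x$dp)) return(x)
  x$gt[x$dp < min_dp] <- NA_integer_
  x
}

#' Require cohort depth support per site
#'
#' Keeps a site only when at least `min_samples` samples report depth
#' strictly above `dp_gt` reads.
#'
#' @param x a `variant_table` with depths.
#' @param dp_gt depth that must be exceeded (strict `>`).
#' @param min_samples required number of supporting samples; values < 1 are
#'   interpreted as a fraction of the cohort.
#' @return the filtered `variant_table`.
#' @export
require_depth_support <- function(x, dp_gt = 10L, min_samples = 96L) {
  stopifnot(inherits(x, "variant_table"))
  if (is.null(x$dp)) stop_("no depth information in table")
  if (min_samples < 1) min_samples <- ceiling(min_samples * n_samples(x))
  if (min_samples > n_samples(x)) {
    stop_("min_samples (%d) exceeds cohort size (%d)", min_samples, n_samples(x))
  }
  keep <- rowSums(x$dp > dp_gt, na.rm = TRUE) >= min_samples
  x[keep]
}

#' Site-level quality, missingness, allele-count and frequency filters
#'
#' Applies, in order: site QUAL >= `min_site_q`; missing genotype fraction
#' <= `max_missing_frac`; minor allele count >= `min_mac`; minor allele
#' frequency >= `min_maf` (frequencies over called genotypes). The four
#' predicates are independent, so the surviving set does not depend on the
#' order; per-filter drop counts are attached as attribute `drop_counts`.
#'
#' @param x a `variant_table` with a `qual` column.
#' @param min_site_q,max_missing_frac,min_mac,min_maf thresholds (see
#'   [filter_config()]).
#' @return the filtered `variant_table`.
#' @export
site_filters <- function(x, min_site_q = 30, max_missing_frac = 0.5,
                         min_mac = 3L, min_maf = 0.05) {
  stopifnot(inherits(x, "variant_table"))
  qual <- x$sites$qual %||% rep(NA_real_, n_sites(x))
  pass_q <- !is.na(qual) & qual >= min_site_q
  pass_miss <- site_missing_frac(x) <= max_missing_frac
  mac <- site_mac(x)
  maf <- site_maf(x)
  pass_mac <- !is.na(mac) & mac >= min_mac
  pass_maf <- !is.na(maf) & maf >= min_maf
  keep <- pass_q & pass_miss & pass_mac & pass_maf
  out <- x[keep]
  attr(out, "drop_counts") <- c(
    site_q = sum(!pass_q),
    missingness = sum(pass_q & !pass_miss),
    mac = sum(pass_q & pass_miss & !pass_mac),
    maf = sum(pass_q & pass_miss & pass_mac & !pass_maf)
  )
  out
}

#' Run the full post-calling filter cascade
#'
#' Order of operations: hard filter on INFO metrics, per-genotype low-depth
#' masking, cohort depth support, then the four site-level filters (minor
#' allele count recomputed after masking).
#'
#' @param x a `variant_table`.
#' @param config a [filter_config()].
#' @return list with `table` (the filtered `variant_table`) and `report`
#'   (data.frame of per-step site counts).
#' @export
filter_cascade <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "variant_table"), inherits(config, "filter_config"))
  steps <- character()
  counts <- integer()
  note <- function(step) {
    steps <<- c(steps, step)
    counts <<- c(counts, n_sites(x))
  }
  note("input")
  x <- x[apply_hard_filter(x, config$hard_filter)]
  note("hard_filter")
  x <- mask_low_depth(x, config$min_dp_genotype)
  note("low_depth_mask")
  if (!is.null(x$dp)) {
    x <- require_depth_support(x, config$support_dp, config$support_min_samples)
  }
  note("depth_support")
  x <- site_filters(
    x, config$min_site_q, config$max_missing_frac,
    config$min_mac, config$min_maf
  )
  note("site_filters")
  list(table = x, report = data.frame(step = steps, n_sites = counts, stringsAsFactors = FALSE))
}
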