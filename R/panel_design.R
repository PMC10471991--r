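new_spet_panel <- function(probes, qc = NULL, rejects = NULL) {
  structure(list(probes = probes, qc = qc, rejects = rejects), class = "spet_panel")
}

#' @export
print.spet_panel <- function(x, ...) {
  p <- x$probes
  cat(sprintf("spet_panel: %d probes", nrow(p)))
  if (nrow(p)) {
    cat(sprintf(
      " (%d genic, %d intergenic; %d rescued in design round 2)",
      sum(p$class == "genic"), sum(p$class == "intergenic"),
      sum(p$design_round == 2L)
    ))
  }
  cat("\n")
  if (!is.null(x$rejects) && nrow(x$rejects)) {
    cat(sprintf("  %d target(s) rejected (no unique N-free probe)\n", nrow(x$rejects)))
  }
  if (!is.null(x$qc)) {
    cat(sprintf("  mean inter-probe spacing: %.1f kbp\n", x$qc$mean_interprobe_spacing_kbp))
  }
  invisible(x)
}

#' Filter variants by minor allele count
#'
#' The minor allele count is computed over called genotypes only (a het
#' contributes 1 and a hom-alt 2 to the alt count). The default `min_mac = 3`
#' keeps sites supported by at least one homozygous plus one heterozygous
#' carrier, or three heterozygous carriers. Sites with zero called genotypes
#' are excluded with a warning.
#'
#' @param x a `variant_table`.
#' @param min_mac minimum minor allele count.
#' @return the filtered `variant_table` (site order preserved).
#' @export
filter_by_allele_count <- function(x, min_mac = 3L) {
  stopifnot(inherits(x, "variant_table"), min_mac >= 0)
  called <- site_called(x)
  if (any(called == 0L)) {
    warn_("%d site(s) with zero called genotypes excluded", sum(called == 0L))
  }
  keep <- called > 0L & site_mac(x) >= min_mac
  x[keep]
}

#' Build the gene space from gene models
#'
#' Each gene is extended on its 5' side by `up` bp and on its 3' side by
#' `down` bp (strand-aware: for a `-` strand gene the 5' side is the higher
#' coordinate). Extended intervals are clipped to the chromosome and merged.
#'
#' @param genes gene model data.frame as from [read_gff_genes()].
#' @param chrom_lengths named chromosome lengths (bp).
#' @param up,down extension in bp (defaults 5000 upstream, 1000 downstream).
#' @return a [GenomicRanges::GRanges] of merged gene-space intervals.
#' @export
build_gene_space <- function(genes, chrom_lengths, up = 5000L, down = 1000L) {
  stopifnot(up >= 0, down >= 0)
  unknown <- setdiff(unique(genes$chrom), names(chrom_lengths))
  if (length(unknown)) stop_("gene(s) on unknown chromosome: %s", paste(unknown, collapse = ", "))
  if (nrow(genes) == 0L) {
    return(GenomicRanges::GRanges(seqlengths = chrom_lengths))
  }
  plus <- genes$strand == "+"
  start0 <- ifelse(plus, genes$start0 - up, genes$start0 - down)
  end0 <- ifelse(plus, genes$end0 + down, genes$end0 + up)
  start0 <- pmax(start0, 0)
  end0 <- pmin(end0, unname(chrom_lengths[genes$chrom]))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    seqlengths = chrom_lengths[unique(genes$chrom)]
  )
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Convert a gene-space GRanges to a 0-based half-open data.frame
#' @param gene_space result of [build_gene_space()].
#' @return data.frame with `chrom`, `start0`, `end0`.
#' @export
gene_space_df <- function(gene_space) {
  data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gene_space)),
    start0 = BiocGenerics::start(gene_space) - 1L,
    end0 = BiocGenerics::end(gene_space),
    stringsAsFactors = FALSE
  )
}

#' Label variants as genic or intergenic
#'
#' A variant is genic iff its position lies inside a gene-space interval.
#' Variants on chromosomes absent from the gene space are labeled intergenic
#' with a warning.
#'
#' @param x a `variant_table`.
#' @param gene_space result of [build_gene_space()].
#' @return `x` with a `class` column (`"genic"`/`"intergenic"`) added to
#'   `x$sites`.
#' @export
classify_variants <- function(x, gene_space) {
  stopifnot(inherits(x, "variant_table"))
  known <- GenomeInfoDb::seqlevels(gene_space)
  off <- !(x$sites$chrom %in% known)
  if (any(off)) {
    warn_(
      "%d variant(s) on chromosome(s) absent from gene space labeled intergenic",
      sum(off)
    )
  }
  lab <- rep("intergenic", n_sites(x))
  if (any(!off) && length(gene_space)) {
    q <- GenomicRanges::GRanges(
      seqnames = x$sites$chrom[!off],
      ranges = IRanges::IRanges(start = x$sites$pos0[!off] + 1L, width = 1L)
    )
    hit <- GenomicRanges::countOverlaps(q, gene_space, ignore.strand = TRUE) > 0
    lab[!off][hit] <- "genic"
  }
  x$sites$class <- lab
  x
}

#' Select target sites under class-specific spacing constraints
#'
#' Within each chromosome and each class independently, targets are chosen by
#' a greedy left-to-right scan: keep the first candidate, then every next
#' candidate at least the class distance from the last kept one (this greedy
#' rule attains the maximum number of compatible sites). If the total exceeds
#' `cap`, the panel is thinned deterministically by repeatedly dropping the
#' right-hand member of the closest same-class same-chromosome pair.
#'
#' @param x a classified `variant_table` (see [classify_variants()]).
#' @param d_genic minimum spacing between genic targets (bp).
#' @param d_intergenic minimum spacing between intergenic targets (bp).
#' @param cap maximum panel size.
#' @return data.frame of targets: `target_id`, `chrom`, `pos0`, `ref`, `alt`,
#'   `class`, `minor_allele_count`.
#' @export
select_targets <- function(x, d_genic = 3000L, d_intergenic = 200000L, cap = 50000L) {
  stopifnot(inherits(x, "variant_table"))
  if (is.null(x$sites$class)) stop_("variants are not classified; run classify_variants() first")
  if (n_sites(x) == 0L) {
    return(data.frame(
      target_id = character(), chrom = character(), pos0 = integer(),
      ref = character(), alt = character(), class = character(),
      minor_allele_count = integer(), stringsAsFactors = FALSE
    ))
  }
  s <- x$sites
  s$minor_allele_count <- site_mac(x)
  dmin <- c(genic = d_genic, intergenic = d_intergenic)
  keep <- logical(nrow(s))
  for (ch in unique(s$chrom)) {
    for (cl in c("genic", "intergenic")) {
      idx <- which(s$chrom == ch & s$class == cl)
      if (!length(idx)) next
      keep[idx] <- greedy_space(s$pos0[idx], dmin[[cl]])
    }
  }
  sel <- s[keep, c("chrom", "pos0", "ref", "alt", "class", "minor_allele_count")]
  sel <- sel[order(chrom_order(sel$chrom, unique(s$chrom)), sel$pos0), , drop = FALSE]
  sel <- thin_to_cap(sel, cap)
  sel$target_id <- sprintf("T%06d", seq_len(nrow(sel)))
  rownames(sel) <- NULL
  sel[, c("target_id", "chrom", "pos0", "ref", "alt", "class", "minor_allele_count")]
}

## greedy "keep first, then first compatible" scan on sorted positions
greedy_space <- function(pos, dmin) {
  stopifnot(!is.unsorted(pos))
  keep <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos)) {
    if (pos[i] - last >= dmin) {
      keep[i] <- TRUE
      last <- pos[i]
    }
  }
  keep
}

## iteratively drop the right member of the globally closest same-class,
## same-chromosome pair until n <= cap
thin_to_cap <- function(sel, cap) {
  while (nrow(sel) > cap) {
    gap <- Inf
    drop_i <- NA_integer_
    for (cl in unique(sel$class)) {
      idx <- which(sel$class == cl)
      if (length(idx) < 2L) next
      same <- sel$chrom[idx[-1L]] == sel$chrom[idx[-length(idx)]]
      d <- sel$pos0[idx[-1L]] - sel$pos0[idx[-length(idx)]]
      d[!same] <- Inf
      if (length(d) && min(d) < gap) {
        gap <- min(d)
        drop_i <- idx[-1L][which.min(d)]
      }
    }
    if (is.na(drop_i)) break
    sel <- sel[-drop_i, , drop = FALSE]
  }
  sel
}

#' Count exact occurrences of a probe sequence in a genome
#'
#' Occurrences of `seq` and of its reverse complement are counted over all
#' chromosomes (overlapping matches counted; a self-reverse-complementary
#' sequence is counted once per location).
#'
#' @param seq nucleotide string over A/C/G/T.
#' @param genome named `DNAStringSet`.
#' @return integer occurrence count.
#' @export
probe_uniqueness <- function(seq, genome) {
  if (!is_string(seq) || grepl("[^ACGT]", seq)) stop_("probe sequence must be a string over A,C,G,T")
  pat <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(pat)
  n_fwd <- sum(Biostrings::vcountPattern(pat, genome))
  if (as.character(rc) == seq) {
    return(n_fwd)
  }
  n_fwd + sum(Biostrings::vcountPattern(rc, genome))
}

#' Design a probe for one target site
#'
#' Round 1 places a plus-strand probe of length `L` at
#' `[pos0 - L - floor(W/2), pos0 - floor(W/2))` so the target sits mid-way in
#' the `W`-bp capture window downstream of the probe 3' end. If that k-mer
#' contains N, runs off the chromosome, or is not unique in the genome,
#' round 2 slides the probe in 10-bp steps over all offsets that keep the
#' target inside the window, then tries the minus strand symmetrically; the
#' first unique N-free placement wins.
#'
#' @param chrom,pos0 target location (0-based).
#' @param genome named `DNAStringSet`.
#' @param L probe length (bp).
#' @param W capture window length downstream of the probe 3' end (bp).
#' @return one-row data.frame (`probe_start0`, `probe_end0`, `probe_strand`,
#'   `probe_seq`, `design_round`, `uniqueness_count`) or `NULL` when no valid
#'   placement exists.
#' @export
design_probe <- function(chrom, pos0, genome, L = 40L, W = 460L) {
  if (!chrom %in% names(genome)) stop_("target on unknown chromosome %s", chrom)
  clen <- length(genome[[chrom]])
  if (pos0 < 0 || pos0 >= clen) stop_("target position outside chromosome %s", chrom)
  half <- W %/% 2L

  try_placement <- function(start0, strand, round) {
    end0 <- start0 + L
    if (start0 < 0 || end0 > clen) return(NULL)
    fwd <- as.character(Biostrings::subseq(genome[[chrom]], start0 + 1L, end0))
    if (grepl("N", fwd, fixed = TRUE)) return(NULL)
    seq <- if (strand == "+") fwd else revcomp(fwd)
    n <- probe_uniqueness(seq, genome)
    if (n != 1L) return(NULL)
    data.frame(
      probe_start0 = start0, probe_end0 = end0, probe_strand = strand,
      probe_seq = seq, design_round = round, uniqueness_count = n,
      stringsAsFactors = FALSE
    )
  }

  ## round 1: centered, plus strand
  hit <- try_placement(pos0 - L - half, "+", 1L)
  if (!is.null(hit)) return(hit)
  ## round 2: slide on plus strand (probe_end in (pos0 - W, pos0]),
  ## then minus strand (probe_start in (pos0, pos0 + W])
  for (d in seq(0L, W - 1L, by = 10L)) {
    hit <- try_placement(pos0 - d - L, "+", 2L)
    if (!is.null(hit)) return(hit)
  }
  for (d in seq(0L, W - 1L, by = 10L)) {
    hit <- try_placement(pos0 + 1L + d, "-", 2L)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Design a full SPET panel
#'
#' Runs the whole design pipeline: minor-allele-count filter, gene-space
#' construction and labeling, class-specific distance-constrained target
#' selection, per-target probe design with uniqueness rescue, and QC.
#'
#' @param x cohort `variant_table`.
#' @param genes gene models (see [read_gff_genes()]).
#' @param genome named `DNAStringSet`.
#' @param min_mac minimum minor allele count for candidate variants.
#' @param up,down gene-space extension (bp).
#' @param d_genic,d_intergenic class spacing constraints (bp).
#' @param cap maximum panel size.
#' @param L,W probe length and capture window (bp).
#' @return a `spet_panel`: `probes` (targets + probes), `rejects`
#'   (targets with no valid probe) and `qc` ([panel_qc()] report).
#' @export
design_panel <- function(x, genes, genome,
                         min_mac = 3L, up = 5000L, down = 1000L,
                         d_genic = 3000L, d_intergenic = 200000L,
                         cap = 50000L, L = 40L, W = 460L) {
  lens <- chrom_lengths(genome)
  x <- filter_by_allele_count(x, min_mac)
  gs <- build_gene_space(genes, lens, up, down)
  x <- classify_variants(x, gs)
  targets <- select_targets(x, d_genic, d_intergenic, cap)
  probes <- vector("list", nrow(targets))
  ok <- logical(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    p <- design_probe(targets$chrom[i], targets$pos0[i], genome, L, W)
    if (!is.null(p)) {
      probes[[i]] <- p
      ok[i] <- TRUE
    }
  }
  kept <- cbind(targets[ok, , drop = FALSE], do.call(rbind, probes[ok]))
  rownames(kept) <- NULL
  rejects <- targets[!ok, , drop = FALSE]
  rejects$reason <- if (nrow(rejects)) "no unique N-free probe placement" else character(0)
  panel <- new_spet_panel(kept, rejects = rejects)
  panel$qc <- panel_qc(panel, lens)
  panel
}

#' Panel quality-control report
#'
#' Reports the mean inter-probe spacing (total genome length / number of
#' targets), the distribution of successive same-chromosome gaps (fraction
#' over 50 kbp, largest gap and its location) and per-1-Mbp probe counts per
#' chromosome.
#'
#' @param panel a `spet_panel`.
#' @param chrom_lengths named chromosome lengths (bp).
#' @return a list of class `panel_qc_report`.
#' @export
panel_qc <- function(panel, chrom_lengths) {
  p <- panel$probes
  if (nrow(p) == 0L) stop_("empty panel")
  n <- nrow(p)
  gaps <- data.frame(chrom = character(), start0 = integer(), gap = integer())
  per_mb <- list()
  for (ch in unique(p$chrom)) {
    pos <- sort(p$pos0[p$chrom == ch])
    if (length(pos) > 1L) {
      g <- diff(pos)
      gaps <- rbind(gaps, data.frame(chrom = ch, start0 = pos[-length(pos)], gap = g))
    }
    breaks <- seq(0, chrom_lengths[[ch]] + 1e6, by = 1e6)
    per_mb[[ch]] <- as.integer(table(cut(pos, breaks, right = FALSE)))
  }
  max_i <- if (nrow(gaps)) which.max(gaps$gap) else NA_integer_
  structure(list(
    n_targets = n,
    n_genic = sum(p$class == "genic"),
    n_intergenic = sum(p$class == "intergenic"),
    mean_interprobe_spacing_kbp = sum(as.numeric(chrom_lengths)) / n / 1000,
    fraction_gaps_over_50kbp = if (nrow(gaps)) mean(gaps$gap > 50000) else NA_real_,
    max_gap_bp = if (nrow(gaps)) gaps$gap[max_i] else NA_integer_,
    max_gap_location = if (nrow(gaps)) sprintf("%s:%d", gaps$chrom[max_i], gaps$start0[max_i]) else NA_character_,
    probes_per_mbp = per_mb
  ), class = "panel_qc_report")
}

#' @export
print.panel_qc_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "panel QC: %d targets (%d genic, %d intergenic)\n",
      "  mean inter-probe spacing: %.1f kbp\n",
      "  fraction of gaps > 50 kbp: %.3f\n",
      "  largest gap: %s bp at %s\n"
    ),
    x$n_targets, x$n_genic, x$n_intergenic,
    x$mean_interprobe_spacing_kbp, x$fraction_gaps_over_50kbp,
    format(x$max_gap_bp, big.mark = ","), x$max_gap_location
  ))
  invisible(x)
}
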