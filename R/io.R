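#' Read a reference genome from FASTA
#'
#' Sequences are upcased; record order is preserved. Only A/C/G/T/N are
#' accepted.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  genome <- Biostrings::readDNAStringSet(path)
  if (length(genome) == 0L) stop_("no sequences in %s", path)
  nm <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(nm)) {
    stop_("duplicate sequence name(s): %s", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(genome) <- nm
  bad <- Biostrings::alphabetFrequency(genome)[, setdiff(colnames(Biostrings::alphabetFrequency(genome)), c("A", "C", "G", "T", "N")), drop = FALSE]
  if (any(bad > 0)) stop_("sequences contain letters outside A,C,G,T,N")
  genome
}

#' Write a genome to FASTA
#' @param genome named `DNAStringSet` (or named character vector).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Chromosome lengths of a genome
#' @param genome named `DNAStringSet`.
#' @return named integer vector of sequence lengths.
#' @export
chrom_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Read gene models from a GFF3 file
#'
#' Only features of type `gene` are consumed. GFF3 1-based inclusive
#' coordinates are converted to the package-internal 0-based half-open
#' convention.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start0`, `end0`
#'   (0-based half-open) and `strand` (`+`/`-`), sorted per chromosome.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    return(data.frame(
      gene_id = character(), chrom = character(),
      start0 = integer(), end0 = integer(), strand = character(),
      stringsAsFactors = FALSE
    ))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop_("gene with unknown strand in %s", path)
  id <- gr$ID
  if (is.null(id) || anyNA(id)) stop_("gene feature without ID attribute in %s", path)
  if (anyDuplicated(id)) stop_("duplicate gene_id in %s", path)
  genes <- data.frame(
    gene_id = as.character(id),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start0 = BiocGenerics::start(gr) - 1L,
    end0 = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  if (any(genes$end0 <= genes$start0)) stop_("gene with end < start in %s", path)
  genes <- genes[order(chrom_order(genes$chrom), genes$start0), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Read a multi-sample VCF into a variant table
#'
#' GT is recoded to alt-allele dosage (`0/0` -> 0, `0/1` or `1/0` -> 1,
#' `1/1` -> 2, `./.` -> `NA`); phased separators are accepted. Multi-allelic
#' records are dropped (the count is reported in attribute
#' `n_multiallelic_dropped` and via a message). Per-sample DP and the INFO
#' fields `QD`, `MQ`, `MQRankSum` are carried along when present.
#'
#' @param path VCF 4.x file (plain or gzipped).
#' @return a [variant_table()]; 1-based VCF POS becomes 0-based `pos0`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop_("no variant records in %s", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0) {
    message(sprintf("read_vcf: dropped %d multi-allelic record(s)", n_multi))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  samples <- colnames(v@gt)[-1L]
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow = nrow(gt_raw), ncol = ncol(gt_raw))
  norm <- gsub("|", "/", gt_raw, fixed = TRUE)
  code[norm %in% "0/0"] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm %in% "1/1"] <- 2L
  bad <- !is.na(norm) & !(norm %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop_(
      "malformed GT '%s' at %s:%s sample %s",
      gt_raw[w[1L], w[2L]], fix$CHROM[w[1L]], fix$POS[w[1L]], samples[w[2L]]
    )
  }
  dp <- NULL
  fmt <- strsplit(v@gt[, 1L], ":", fixed = TRUE)
  if (all(vapply(fmt, function(f) "DP" %in% f, logical(1L)))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    dp[is.na(dp)] <- 0
    dimnames(dp) <- NULL
  }
  info_num <- function(field) suppressWarnings(vcfR::extract.info(v, element = field, as.numeric = TRUE))
  sites <- data.frame(
    chrom = fix$CHROM,
    pos0 = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    QD = info_num("QD"),
    MQ = info_num("MQ"),
    MQRankSum = info_num("MQRankSum"),
    stringsAsFactors = FALSE
  )
  out <- variant_table(sites, code, dp, samples)
  attr(out, "n_multiallelic_dropped") <- n_multi
  out
}

#' Write a variant table to a VCF 4.2 file
#'
#' Emits GT (and DP when present) per sample and the INFO fields `QD`, `MQ`
#' and `MQRankSum` where they are non-missing. Internal 0-based positions are
#' written back as 1-based POS.
#'
#' @param x a `variant_table`.
#' @param path output file.
#' @param contig_lengths optional named lengths for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  stopifnot(inherits(x, "variant_table"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=spet",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", x$samples), collapse = "\t"))
  s <- x$sites
  fmt_num <- function(v) ifelse(is.na(v), NA, format(v, trim = TRUE, scientific = FALSE, digits = 6))
  info <- apply(
    cbind(
      QD = if ("QD" %in% names(s)) fmt_num(s$QD) else NA,
      MQ = if ("MQ" %in% names(s)) fmt_num(s$MQ) else NA,
      MQRankSum = if ("MQRankSum" %in% names(s)) fmt_num(s$MQRankSum) else NA
    ),
    1L,
    function(r) {
      keep <- !is.na(r)
      if (!any(keep)) "." else paste(sprintf("%s=%s", names(r)[keep], r[keep]), collapse = ";")
    }
  )
  gt_str <- matrix(".\\.", nrow = n_sites(x), ncol = n_samples(x))
  gt_str[] <- c("0/0", "0/1", "1/1")[x$gt + 1L]
  gt_str[is.na(x$gt)] <- "./."
  if (!is.null(x$dp)) {
    fmt <- "GT:DP"
    gt_str[] <- paste(gt_str, ifelse(is.na(x$dp), ".", x$dp), sep = ":")
  } else {
    fmt <- "GT"
  }
  body <- paste(
    s$chrom, s$pos0 + 1L, ".", s$ref, s$alt,
    ifelse(is.na(s$qual %||% NA), ".", fmt_num(s$qual %||% NA)), "PASS", info, fmt,
    apply(gt_str, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write panel files (probe FASTA, target BED, panel TSV)
#'
#' Three files are produced: `<prefix>_probes.fasta` (probe sequences as
#' synthesized), `<prefix>_targets.bed` (0-based half-open single-base target
#' intervals) and `<prefix>_panel.tsv` (1-based coordinates in the table).
#'
#' @param panel a `spet_panel` (see [design_panel()]).
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  stopifnot(inherits(panel, "spet_panel"))
  p <- panel$probes
  files <- c(
    fasta = paste0(prefix, "_probes.fasta"),
    bed = paste0(prefix, "_targets.bed"),
    tsv = paste0(prefix, "_panel.tsv")
  )
  if (nrow(p)) {
    write_fasta(setNames(Biostrings::DNAStringSet(p$probe_seq), p$target_id), files[["fasta"]])
  } else {
    writeLines(character(), files[["fasta"]])
  }
  bed <- if (nrow(p)) {
    paste(p$chrom, p$pos0, p$pos0 + 1L, p$target_id, sep = "\t")
  } else {
    character()
  }
  writeLines(bed, files[["bed"]])
  tsv <- data.frame(
    target_id = p$target_id,
    chrom = p$chrom,
    target_pos_1based = p$pos0 + 1L,
    class = p$class,
    probe_start_1based = p$probe_start0 + 1L,
    probe_strand = p$probe_strand,
    probe_seq = p$probe_seq,
    design_round = p$design_round,
    stringsAsFactors = FALSE
  )
  write.table(tsv, files[["tsv"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(files)
}

#' Read a panel TSV back into a `spet_panel`
#'
#' Inverse of the TSV component of [write_panel()]; probe intervals are
#' reconstructed from the 1-based probe start and the probe length.
#'
#' @param path panel TSV written by [write_panel()].
#' @return a `spet_panel` (without QC report or rejects).
#' @export
read_panel_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  L <- if (nrow(d)) nchar(d$probe_seq) else integer()
  probes <- data.frame(
    target_id = as.character(d$target_id),
    chrom = as.character(d$chrom),
    pos0 = as.integer(d$target_pos_1based) - 1L,
    class = as.character(d$class),
    probe_start0 = as.integer(d$probe_start_1based) - 1L,
    probe_end0 = as.integer(d$probe_start_1based) - 1L + L,
    probe_strand = as.character(d$probe_strand),
    probe_seq = as.character(d$probe_seq),
    design_round = as.integer(d$design_round),
    stringsAsFactors = FALSE
  )
  new_spet_panel(probes)
}
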