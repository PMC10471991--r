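# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# Minimal variant table from a genotype matrix (sites x samples); NA = missing.
toy_table <- function(gt, pos0 = NULL, chrom = "chr1", qual = 100,
                      ref = "A", alt = "G", dp = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  sites <- data.frame(
    chrom = rep_len(chrom, n),
    pos0 = if (is.null(pos0)) seq_len(n) * 100L else pos0,
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n),
    stringsAsFactors = FALSE
  )
  variant_table(sites, gt, dp = dp)
}

# Deterministic tiny genome from explicit sequences.
toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

# Brute-force maximum number of positions selectable under a minimum-spacing
# constraint (exhaustive subset search; oracle for the greedy selector).
max_spaced_subset <- function(pos, dmin) {
  pos <- sort(pos)
  n <- length(pos)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- pos[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (length(sel) <= best) next
    if (length(sel) < 2L || all(diff(sel) >= dmin)) best <- length(sel)
  }
  best
}

# Naive sliding-window occurrence count of a k-mer (both strands) in a genome
# given as character vector; oracle for probe_uniqueness().
naive_kmer_count <- function(seq, chroms) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  pats <- unique(c(seq, rc))
  total <- 0L
  for (s in chroms) {
    L <- nchar(seq)
    for (i in seq_len(nchar(s) - L + 1L)) {
      w <- substr(s, i, i + L - 1L)
      if (w %in% pats) total <- total + 1L
    }
  }
  total
}
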