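`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Reverse complement of a nucleotide string
#' @noRd
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## Chromosome order = order of first appearance (reference order), not
## lexicographic: "chr10" must not sort before "chr2".
chrom_order <- function(chrom, levels = unique(chrom)) {
  factor(chrom, levels = levels)
}
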