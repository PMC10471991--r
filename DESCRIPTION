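Package: spet
Title: Targeted Genotyping Panel Design and Population Genomics for
    Single Primer Enrichment Technology Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and analysing single primer enrichment
    technology (SPET) genotyping panels. Builds a distance-constrained,
    gene-space-enriched target panel from a cohort VCF, a gene annotation
    and a reference genome (40-bp probes with a 460-bp capture window and
    genome-wide uniqueness checks); applies a post-calling genotype filter
    cascade (hard-filter expressions on INFO metrics, per-genotype depth
    masking, cohort depth support, minor-allele-count, missingness, quality
    and frequency filters); computes diversity and structure statistics
    (expected heterozygosity, polymorphic information content, windowed
    nucleotide diversity, Ts/Tv, per-sample heterozygosity, SNP spacing,
    Hudson and Weir-Cockerham FST, identity-by-state kinship, PCA); and runs
    a baseline single-marker general linear model association scan with
    Bonferroni control and nearest-gene annotation. Seeded simulators
    generate every input the toolkit consumes, including structured cohorts
    under the Balding-Nichols model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    graphics,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
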