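---
title: "Methods: SPET panel design and downstream population genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPET panel design and downstream population genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

Single primer enrichment technology (SPET) genotypes a cohort by hybridizing
one short probe (here 40 bp) per target locus and sequencing a fixed window
(here 460 bp) downstream of the probe's 3' end. The package covers the four
computational stages around such an assay:

1. **Panel design** — choose target variants from a cohort VCF, enriched for
   the gene space, under class-specific spacing constraints, and design a
   unique probe per target.
2. **Genotype filtering** — the standard post-calling cascade on the
   genotyped cohort.
3. **Diversity and structure statistics** — allele-frequency summaries,
   windowed nucleotide diversity, FST, identity-by-state kinship, PCA.
4. **Association scan** — a baseline single-marker general linear model with
   Bonferroni family-wise control and nearest-gene annotation.

All internal coordinates are 0-based half-open; conversion to the 1-based
inclusive conventions of GFF3/VCF/TSV, and to 0-based half-open BED, happens
only in the readers and writers. This single contract is what the round-trip
tests assert.

## Panel design

**Gene space.** Gene bodies are extended 5,000 bp on the 5' side and
1,000 bp on the 3' side, then clipped to the chromosome and merged. The
extension is strand-aware: the annotation itself does not dictate a side,
but the strong 5'/3' asymmetry of the defaults (5 kb vs 1 kb) indicates
promoter-side intent, so for a minus-strand gene the 5-kb extension is
applied at the higher coordinate. A variant is *genic* iff its position
falls inside a merged interval (half-open membership, so an interval end is
already intergenic).

**Candidate filter.** Candidates must reach a minor allele count of 3 over
called genotypes — one homozygous plus one heterozygous carrier, or three
heterozygous carriers. The count is computed on the minor allele, so
near-fixed alt alleles are excluded symmetrically.

**Target selection.** Within each chromosome, genic targets must be at
least 3 kb apart and intergenic targets at least 200 kb apart; the two
classes are spaced independently (the class distances are defined per
class, and cross-class proximity is deliberately allowed). Selection is the
greedy left-to-right scan — keep the first candidate, then every next
candidate compatible with the last kept one — which is the classic optimal
strategy for maximizing the number of points under a minimum-spacing
constraint; the test suite verifies greedy counts against an exhaustive
subset search on small instances. If the panel exceeds the cap (default
50,000), it is thinned by repeatedly deleting the right-hand member of the
closest same-class pair, a deterministic rule chosen so repeated runs are
byte-identical.

**Probe design.** Round 1 places a plus-strand probe of length `L` at
`[pos - L - floor(W/2), pos - floor(W/2))`, so that the target sits mid-way
inside the `W`-bp capture window that begins at the probe's 3' end. If that
40-mer contains N, falls off the chromosome, or occurs more than once in
the genome (counting both strands), round 2 slides the probe in 10-bp steps
over every offset that keeps the target inside the window, then mirrors the
search onto the minus strand; the first unique, N-free placement wins and
is recorded as `design_round = 2`. Targets with no valid placement are
reported in a rejects table rather than silently dropped. Uniqueness is
exact 40-mer matching on both strands (via Biostrings pattern counting);
there is no near-match or thermodynamic screen — a documented limitation
relative to vendor design pipelines, which score hybridization energetics
we do not model.

**QC.** The panel report gives the mean inter-probe spacing (total genome
length divided by target count), the fraction of successive same-chromosome
gaps above 50 kbp, the largest gap and its location, and per-1-Mbp probe
counts per chromosome.

## Genotype filtering

The cascade reproduces the standard post-calling pipeline:

1. **Hard filter** on site INFO metrics, default
   `QD<2.0||MQ<40.0||MQRankSum<-12.5`. A site fails if *any* clause whose
   field is present evaluates true; a clause whose field is absent at a
   site is skipped, mirroring the upstream caller's behavior of not
   penalizing unannotated sites.
2. **Low-depth masking**: genotypes backed by *fewer than* 5 reads become
   missing (`depth < 5`, strict — depth 5 survives).
3. **Cohort depth support**: a site is kept only if at least 96 samples (or
   a configured fraction of the cohort) report coverage *above* 10 reads
   (`depth > 10`, strict — exactly 10 does not count).
4. **Site filters**: QUAL ≥ 30, missing fraction ≤ 0.5, minor allele count
   ≥ 3, minor allele frequency ≥ 5% — four independent predicates, so the
   surviving set is order-invariant; the tests assert this commutativity
   against an independent re-implementation, plus idempotence of the whole
   cascade and monotonicity in every threshold.

The boundary semantics (strict vs non-strict) follow the wording of the
filter definitions, and "max missing 0.5" is interpreted as *missing
fraction ≤ 0.5* (numerically identical to the VCFtools `--max-missing`
called-fraction convention at this threshold). The minor allele count is
recomputed after depth masking, matching the order in which the upstream
tools are applied.

## Diversity statistics

For a biallelic site with allele frequencies `p + q = 1` over called
genotypes:

- expected heterozygosity `H = 1 - p^2 - q^2`,
- polymorphic information content `PIC = H - 2 p^2 q^2`.

Both are maximal at `p = 0.5` (`H = 0.5`, `PIC = 0.375`), and `PIC ≤ H`
everywhere; the tests check the full frequency grid. Note that with a MAF
≥ 5% filter in force the analytic floor of PIC is ≈ 0.09 under this
formula, so reported PIC minima below that for filtered data (as sometimes
appears in the applied literature) cannot arise from the printed formula;
the package implements the formula as stated and leaves such
inconsistencies to the reader.

**Windowed π** uses the unbiased per-site pairwise heterozygosity
`π_s = 2 j (c - j) / (c (c - 1))` (`j` alt allele count, `c` called
alleles), summed over the sites of each non-overlapping window and divided
by the window size in bp — the VCFtools `--window-pi` convention, with
1-kb windows by default. Summing `π · window` over windows returns the
per-site total exactly (conservation, asserted in tests).

**FST** defaults to the Hudson estimator with finite-sample correction,
combined across sites as a ratio of averages — unbiased with respect to
sample size and exact at the fixation limit (two groups fixed for
alternate alleles give exactly 1). On two groups with literally identical
genotype counts the corrected numerator is slightly negative rather than
exactly zero; this is the standard behavior of the corrected estimator and
the tests assert near-zero rather than zero. A Weir–Cockerham estimator is
available via `estimator = "wc"`. Sites where a pair of groups is jointly
monomorphic are skipped. Model-based ancestry estimation (and the FST
between inferred ancestral populations it reports) is out of scope.

**IBS kinship** is `K_ij = mean((2 - |g_i - g_j|) / 2)` over mutually
called sites; **per-sample heterozygosity** is the percentage of het calls
among called sites; **Ts/Tv** counts A↔G and C↔T as transitions. **PCA**
mean-centers genotypes per site (missing values replaced by the site mean,
i.e. centered to zero — the only place the package imputes anything) and
eigendecomposes the sample covariance.

## Association scan

The baseline scan fits, per site, ordinary least squares
`y = μ + C β + g γ` with `g` the minor-allele dosage and `C` optional
structure covariates (typically leading PCs), and reports the two-sided
t-test of `γ = 0`. The per-marker significance threshold is Bonferroni:
`α / m` over the `m` tested markers (default `α = 0.05`); for 81,531
markers this gives `p < 6.133e-7`, i.e. `-log10 p > 6.212`. PVE is the
incremental R² of the marker over the covariate-only model on the same
samples — a definition chosen because "variance explained" is otherwise
ambiguous in a covariate-adjusted scan. Effects are reported for the minor
allele (dosage flipped where alt is major). Ordinal trait scores are
treated as numeric, as the standard GLM scan tools do. Sites with fewer
than three distinct genotype values after missing-data removal are skipped
by default (`min_classes = 3`); a 0/2-only site is statistically testable,
so this can be relaxed to 2.

Without covariates the scan is verified, site by site, against `lm()`'s
closed-form simple regression; with covariates against the incremental-R²
definition. Family-wise error on seeded null scans and the recovery of a
spiked causal marker are asserted as distributional properties (below).

**Nearest-gene annotation** reports 0 for hits inside a gene body,
otherwise the signed distance to the nearest gene boundary (positive
downstream of a gene end, negative upstream of a start), ties broken
toward the smaller gene identifier so results are deterministic.

Mixed-model and multi-locus methods (MLM, MLMM, CMLM, FarmCPU, BLINK) are
published third-party algorithms and are not re-implemented; the scan's
output schema (chrom, position, MAF, effect, SE, p, PVE) is a superset of
what those tools emit, so externally computed results can be merged into
multi-model tables.

## Simulators

The generators produce every input the toolkit consumes, deterministically
under a seed (file-hash stable, asserted in tests).

- **Reference**: i.i.d. uniform A/C/G/T; optional planting of duplicated
  40-mers to exercise probe-design rescue.
- **Genes**: non-overlapping, one per equal-width slot, random strand.
- **Cohort**: group allele frequencies follow the Balding–Nichols
  construction — ancestral `p ~ U(0.05, 0.95)`, group frequencies
  `p_k ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` for target differentiation `F` —
  with Hardy–Weinberg genotypes within groups. The defaults mirror the
  assay conditions the package targets: 160 samples, negative-binomial
  depth with mean 80 (deep targeted sequencing; dispersion small enough
  that the depth filters have work to do), a few percent missingness, and
  INFO metrics drawn from pass/fail mixtures so the hard filter is
  exercised. The default divergence target `F = 0.3` sits in the range
  typical of crop germplasm subpopulations.
- **Phenotype**: `y = γ g + group effects + N(0, σ²)` with `γ` derived
  from a target PVE by variance arithmetic; ordinal modes discretize by
  quantile bins. When the structured-dataset wrapper picks a causal site
  itself, it chooses a common site with minimal between-group frequency
  divergence, so the spiked trait is not confounded with the structure
  covariates the scan adjusts for.

Simulated sites are unlinked (no LD), which is the main gap relative to
real resequencing data: power estimates from these fixtures describe the
single-causal-marker case and say nothing about tag-SNP discovery through
LD, and the spacing-constrained selection is not challenged by haplotype
blocks. The simulators also do not model allele-specific capture bias or
probe dropout.

## Problem sizes and numerical choices

The test suite runs at deliberately small scales chosen to keep the
statistical assertions sharp but cheap: toy genomes of 10–100 kb,
cohorts of 10–200 samples, 50–2,000 sites; the family-wise error property
uses 200 null scans of 500 markers at n = 100, and causal-marker recovery
uses 40 replicates of 200 markers at n = 150 with PVE 0.45. Monte-Carlo
tolerances are fixed in advance from binomial/normal error arithmetic
(e.g. the FWER bound is `α + 3·SE` over the replicate count).

Other fixed choices: multi-allelic VCF records are dropped rather than
split (the matrix is defined over biallelic SNPs); phased genotype
separators are accepted and treated as unphased; probes are never allowed
to contain N; all-missing sites yield `NA` statistics, never 0; and every
tie-break (cap-thinning, nearest-gene) is deterministic.
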