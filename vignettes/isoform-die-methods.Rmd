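---
title: "Differential isoform expression from barcoded long reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential isoform expression from barcoded long reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodie)
```

# The problem

Single-cell long-read sequencing yields spliced, barcoded cDNA molecules that
carry a complete isoform observation per read: a transcription start, an
intron chain, and a polyadenylation site. Given such reads from two or more
cell populations (for example, two brain regions, or two cell types within a
region), the questions this package answers are:

1. Which reads are trustworthy, full-length observations of a transcript?
2. Which genes change their isoform *composition* between two groups, and by
   how much?
3. When a bulk-level change is observed, which cell types carry it?
4. Which observed isoforms are genuinely novel relative to the annotation?
5. Do exon-inclusion differences measured in single cells agree in direction
   with spatially resolved long-read data?

# From alignments to CSMMs

Raw alignments pass a fixed filter cascade (`process_reads()`), each stage
logged so the per-stage drop counts add up to the input count:

1. **Alignment selection.** A read's unique alignment is kept if its MAPQ is
   at least 20; with multiple alignments, the best must exceed the runner-up
   by at least 20 MAPQ units.
2. **rRNA removal.** Alignments overlapping an annotated rRNA gene span (any
   overlap, either strand) are dropped. Annotations differ in how they mark
   rRNA, so the flag combines the `rRNA` biotype with a configurable name
   pattern.
3. **Junction snapping.** Long-read aligners place most junctions on
   annotated splice sites, but residual alignment error can shift a junction
   by a few bases. Junctions within the platform tolerance (2 bp PacBio, 3 bp
   ONT) of an annotated donor/acceptor are snapped onto it. Without this
   step, sub-tolerance wobble would fail the motif check below and fragment
   isoform identities; junctions with no annotated site within tolerance are
   left untouched, which is what lets novel junctions survive.
4. **Splice-motif consensus.** A spliced read is kept only if *every* intron
   shows GT-AG, GC-AG or AT-AC dinucleotides (strand-corrected). Reads
   passing are consensus-split-mapped molecules (CSMMs). Unspliced reads are
   excluded by default — the analysis concerns spliced molecules.
5. **Gene assignment.** A CSMM is assigned to the gene with which it shares
   the most annotated splice-site coordinates; ties assign the read to every
   tied gene, flagged ambiguous. By default ambiguous reads are dropped from
   statistics to avoid counting one molecule twice; `drop_ambiguous = FALSE`
   restores per-gene counting of tied reads.
6. **Completeness.** The biological 5' end must fall within 50 bp of a CAGE
   peak and the 3' end within 50 bp of a polyA-site peak. Distance is zero
   inside a peak and otherwise the gap to its nearest boundary; at equal
   distance the more 5' peak wins for the TSS and the more 3' peak for the
   polyA site.
7. **Deconvolution.** Barcodes map to leaf cell types by exact lookup
   (barcode error correction is assumed upstream); unmatched reads stay in
   bulk-level analyses only.

# Isoform identity and the DIE test

Each CSMM is reduced to the string *gene | TSS peak | intron chain | polyA
peak*. Peak identifiers (not raw end coordinates) are used so that benign end
wobble within the matching window does not split one isoform into many;
`key_mode = "raw"` switches to raw coordinates.

For a comparison of two groups, each gene with at least `min_depth = 25`
reads in **each** group is tested:

* counts per isoform form an *n* x 2 table, reduced to at most 11 x 2 by
  keeping the ten most abundant isoforms (pooled over both groups) and
  collapsing the rest into one row;
* a plain Pearson chi-square test with *n* - 1 degrees of freedom (no
  continuity correction) gives the raw p-value;
* the effect size delta-Pi is computed on the *uncollapsed* table: per
  isoform, the difference in its within-gene share between groups; delta-Pi
  is the larger of (sum of the two largest positive shifts) and (absolute sum
  of the two most negative), signed accordingly, with ties going to the
  positive direction. The contributing isoform identities are reported;
* Benjamini-Hochberg adjustment is applied across all testable genes of the
  comparison (comparisons are corrected independently), and each gene's
  correction factor (adjusted/raw before clamping at 1) is recorded;
* a gene is called significant when the adjusted p is at most 0.05 **and**
  |delta-Pi| is at least 0.1.

TSS-only and polyA-only tests follow the identical procedure with the key
reduced to the peak identifier (`feature = "tss"` / `"polya"`).

Because delta-Pi takes a maximum over directions and over isoform subsets, it
is biased upward for weak effects and its direction is undefined when the
positive and negative shifts balance exactly (for example a pure two-isoform
swap). This matters only for sign-matching analyses downstream; magnitudes
and the test itself are unaffected.

# Exon-level test

Exon inclusion is called per read with the platform junction tolerance: an
internal exon is *included* if the read has junctions matching both exon
boundaries within the tolerance, *excluded* if the alignment spans the whole
exon without them, and *discarded* when the read ends inside it. Terminal
exons are judged by coverage: included only when completely covered by read
exonic sequence, excluded when contained in a read intron, otherwise
discarded. Note the asymmetry this inherits from the junction rule: an
inclusion read whose junctions wobble past the tolerance is counted as
excluded, not discarded — the tolerance should therefore not be set below the
platform's alignment error.

Psi is inclusion/(inclusion+exclusion) per group. For two groups, exons with
pooled Psi in [0.1, 0.9] (not effectively constitutive) and expected-count
criterion `min(rowSums) * min(colSums) / total >= 5` are tested by the same
chi-square on the 2 x 2 table. Because exon tests within a gene are
dependent, the Benjamini-Yekutieli correction is used; significance again
requires both the FDR and a |delta-Psi| of at least 0.1.

# Attribution across the cell-type hierarchy

For a gene with a parent-level |delta-Pi| of at least 0.1, each of the two
child groups *participates* if it is testable, has |delta-Pi| at least 0.1,
and points in the same direction as the parent. Both participating gives the
Both-Cell-Types model, exactly one the Single-Cell-Type model, neither (with
both testable) the No-Cell-Type model; an untestable child with a
non-participating sibling yields `insufficient-depth`. Opposite-sign child
changes never explain a parent change, so ratios `dpi_child / dpi_parent` are
sign-matched. Traceability asks whether any *leaf* reaches a ratio of 0.9,
and the concurrence test asks whether |delta-Pi| >= 0.1 co-occurs in two
siblings more often than the product of the marginals, by Fisher's exact
test. TSS directionality counts genes whose focal-group TSS lies upstream
(strand-aware) and reports both the exact symmetric-binomial point
probability and the one-sided tail, since either may be quoted for such
counts.

# Novel isoforms

Candidates are complete, spliced CSMM chains. In order, a candidate is
rejected if (3) its chain equals or is a contiguous subsequence of an
annotated transcript's chain ("truncation"; internal deletions do not count),
(4) an internal exon lacks short-read support of at least 2 on both flanking
junctions, (5) any intron has fewer than 2 supporting spliced short reads, or
(6) it is a contiguous proper subsequence of another surviving novel chain.
The first failed rule is recorded. Accepted isoforms are appended to the
annotation (source `isodie_novel`) with representative read ends, and
per-group counts are written alongside (`write_enhanced_annotation()`),
giving an enhanced annotation whose added isoforms all carry unique,
previously absent intron chains.

# Spatial concordance

Exons with alternative donors/acceptors (flagged by overlap in the exon
catalog) enter the cross-platform comparison only when strictly more than 90%
of their overlapping reads match the exact exon. Concordance between
single-cell and spatial delta-Psi values counts sign agreement (a zero on
either side counts as discordant — a conservative choice the data cannot
adjudicate), reports the exact binomial point probability of the same-sign
count under a fair coin, and the Pearson correlation of the paired values.
Spatial spot reads are pooled per region label before Psi is computed.

# The synthetic-data generator

`simulate_dataset()` builds, from a seed: an annotation (each gene a skeleton
of terminal exons around M internal exons; isoform 1 retains all, isoform j
skips internal exon j-1), a genome with consensus motifs planted at every
junction in use (strand-aware), CAGE/polyA peaks at the transcript ends,
barcode pools per leaf cell type, a short-read junction support table, and
multinomially sampled reads per (gene, sample, cell type). It emulates:

* **Isoform usage.** Per-gene proportions from a sorted symmetric Dirichlet
  (concentration 4 — typical genes have one or two dominant isoforms without
  vanishing minor ones, keeping chi-square expected counts reasonable at the
  default depth of 100 reads per gene per group).
* **Planted effects.** In the second sample, isoform 1 loses `die_dpi`
  probability mass, spread over the remaining isoforms, so the true delta-Pi
  equals `die_dpi`, contributed by one isoform with a well-defined direction.
  Effects can be restricted to chosen cell types for attribution studies.
* **Junction wobble.** Rounded Gaussian shifts clamped at `wobble_max`,
  required not to exceed the platform tolerance so snapping can recover them
  (the recoverable regime; the generator refuses configurations outside it).
* **Truncation.** A configurable fraction of spliced reads (default 5%) lose
  their biological 5' end past the first junction; they fail the completeness
  filter, as real truncated molecules should.
* **Motif corruption.** A configurable fraction of reads have one junction
  displaced 5 bp on both sides — beyond snapping range, landing on random
  sequence, so the read fails the consensus check except when the random
  dinucleotides happen to form a motif (probability 3/256).
* **Novel isoforms.** Planted chains skipping two adjacent internal exons
  (an unannotated junction with support 2), plus two decoys: a truncation of
  the novel chain (rejected by the novel-truncation rule) and a chain with an
  unsupported junction (rejected by the intron-support rule).

The truth ledger records per-read source isoforms, per-group realized counts
and proportions, expected novel-isoform decisions with rule codes, and each
isoform template's exon inclusion status, which suffices to recompute every
pipeline output exactly in the zero-noise limit (`exact_counts = TRUE`
allocates counts by largest remainder and forces all noise to zero).

What the generator does **not** emulate: base-level sequencing error and
chimeras, barcode errors (correction is assumed upstream), UMI duplication,
gene-density effects (genes are laid out without overlap, so gene assignment
ambiguity arises only from shared splice sites in dedicated fixtures), and
realistic peak shapes. Passing tests therefore demonstrate correctness of the
statistics and bookkeeping under the stated read model, not robustness to
raw-signal artifacts.

# Numerical choices and problem sizes

* Coordinates are 0-based half-open throughout; introns are stored as (first
  intronic base, one-past-last), so donor coordinates equal upstream exon
  ends and acceptors equal downstream exon starts, and chains match by
  integer equality after snapping.
* The step-up corrections are implemented directly (cummin over the sorted
  tail) because the per-test pre-clamping correction factor is part of the
  result contract; they are cross-checked against `p.adjust` in the tests.
  The chi-square statistic is likewise computed directly from the classical
  formula and cross-checked against `chisq.test(correct = FALSE)`; Fisher's
  exact test uses `stats::fisher.test`, cross-checked against hypergeometric
  enumeration.
* Rank ties (isoform abundance, equidistant peaks, equal-cost transcript
  assignment) are broken deterministically: canonical string order, the more
  5'/3' peak, the lexicographically smaller transcript id. Delta-Pi direction
  ties go to the positive direction.
* Degenerate inputs: genes with a zero group total or fewer than two
  informative isoform rows are untestable with a recorded reason; all-zero
  rows are dropped before the chi-square; Psi is undefined (and the exon
  untestable) without informative reads.
* Test and example problem sizes were chosen to keep a full run at desk
  scale: 1000 genes x 100 reads/group for the null study, 500 planted genes
  for power, 10-50 genes for end-to-end recovery; the whole suite runs in
  about two minutes.

# Known limitations

* Sign-matching in attribution inherits the delta-Pi direction ambiguity for
  perfectly balanced two-isoform swaps.
* "Terminal" status is resolved per exon (terminal in every transcript
  containing it); an exon internal in one transcript and terminal in another
  is treated as internal.
* Reads that end inside an internal exon are discarded for that exon rather
  than counted fractionally; with heavy 3' truncation this loses power but
  does not bias Psi.
* The completeness filter depends entirely on the supplied CAGE/polyA peak
  sets; with an empty peak file no read is complete, by design.
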