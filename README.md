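# isodie

Cell-type-resolved differential isoform expression (DIE) from spliced,
barcoded long-read alignments.

Single-cell long-read sequencing observes complete transcript structures —
transcription start site (TSS), intron chain, polyadenylation site — one
molecule per read, with a cell barcode attached. `isodie` implements the
downstream analysis for such data: it filters alignments to full-length
consensus-split-mapped molecules (CSMMs), builds per-cell-type isoform
catalogs, tests genes for DIE between any two cell groups, attributes
bulk-level DIE to cell types through a hierarchy, screens novel isoforms
against annotation and short-read support, quantifies exon inclusion (Psi),
and measures directional concordance of splicing differences between
single-cell and spatial long-read data. A seeded synthetic-data generator
with a ground-truth ledger makes every stage testable without external data.

## The statistical core

Each full-length read is reduced to an isoform key
`gene | TSS peak | intron chain | polyA peak`. For two cell groups A and B,
a gene with at least 25 reads in each group yields an *n* x 2 count table
(top ten isoforms plus one collapsed row), tested with a plain Pearson
chi-square (*n* - 1 df). The effect size is the percent-isoform change

&nbsp;&nbsp;&nbsp;&nbsp;ΔΠ = max( sum of the two largest positive Π<sub>i</sub>(A) − Π<sub>i</sub>(B), | sum of the two most negative | )

computed on the uncollapsed table, where Π<sub>i</sub> is isoform *i*'s share
of its gene's reads. Raw p-values are Benjamini–Hochberg corrected per
comparison; a gene is significant when FDR ≤ 0.05 **and** |ΔΠ| ≥ 0.1, and
the contributing isoforms are reported by identity. Exon-level tests use 2x2
inclusion/exclusion tables with Benjamini–Yekutieli correction (dependent
tests) and a |ΔΨ| ≥ 0.1 effect threshold.

## Worked example

Simulate the default study — 50 genes, two samples (HIPP, PFC) by four leaf
cell types, 100 reads per gene per group, 10 genes with a planted ΔΠ = 0.3,
two planted novel isoforms — then run the pipeline and the bulk DIE test:

```r
library(isodie)

cfg <- sim_config(n_genes = 50, n_die_genes = 10, die_dpi = 0.3,
                  novel_genes = 2, depth = 100)
sim <- simulate_dataset(cfg, seed = 1)

pr <- process_reads(sim$reads, sim$genes, sim$genome, sim$cage, sim$polya,
                    sim$cellmap, tolerance = cfg$tolerance)
pr$stages
#>         input mapq_filtered  rrna_overlap non_consensus       no_gene
#>         40000             0             0             6             0
#>    incomplete          csmm
#>          2032         37962

grp <- make_groups(pr$csmm, sim$cellmap,
                   list(node = "bulk", sample = "HIPP", label = "HIPP"),
                   list(node = "bulk", sample = "PFC", label = "PFC"))
res <- die_test(pr$csmm, grp)
res
#> <die_result> isoform test: 50 genes, 50 testable, 11 significant (22%)

head(as.data.frame(res[res$significant,
       c("gene_id", "raw_p", "adj_p", "correction_factor", "dpi")]), 4)
#>   gene_id    raw_p    adj_p correction_factor   dpi
#> 1   G0001 1.20e-20 9.96e-20              8.33 0.322
#> 2   G0002 2.71e-24 4.52e-23             16.67 0.310
#> 3   G0003 5.35e-21 6.69e-20             12.50 0.312
#> 4   G0004 1.65e-18 1.03e-17              6.25 0.320

nv <- discover_novel(pr$csmm, sim$genes, sim$sr_junctions)
sum(nv$accepted)
#> [1] 2
```

Reading the output: the stage log shows ~5% of reads lost to 5'-truncation
(they miss their CAGE peak) and a handful to splice-motif failures. The DIE
test recovers the ten planted genes — estimated ΔΠ near the true 0.3, with
per-gene BH correction factors — plus one borderline null gene, and the
novel-isoform filters accept exactly the two planted chains while rejecting
their truncation and low-support decoys. Attribution of a bulk signal to cell
types proceeds with the same machinery via `attribute_die()`,
`traceability()` and `concurrence_test()`; exon-level quantification via
`call_exons()`, `psi_tables()` and `exon_test()`; and cross-platform
agreement via `eligible_exons()` and `concordance()`.

Real data enter through `load_annotation()` (GTF), `load_genome()` (FASTA),
`load_peaks()` (BED6 CAGE/polyA), `load_cell_map()` (barcode TSV + hierarchy),
`load_junction_support()` (short-read junction TSV), and
`read_alignment_table()` / `read_alignment_bam()` for the long reads.

## Package layout

- `R/annotation_io.R` — GTF/BED/FASTA/TSV readers, the internal 0-based
  half-open coordinate convention, the `gene_set` container.
- `R/read_processing.R` — the CSMM filter cascade (MAPQ selection, rRNA
  removal, junction snapping, splice-motif consensus, gene assignment,
  CAGE/polyA completeness, barcode deconvolution).
- `R/isoform_catalog.R` — isoform keys, usage tables, top-k collapse,
  annotated-transcript assignment, novel-isoform rules, enhanced annotation.
- `R/exon_quant.R` — per-read exon calls with platform tolerance, Psi tables.
- `R/die_tests.R` — chi-square n x 2 test, ΔΠ, BH/BY step-up with correction
  factors, gene- and exon-level test drivers.
- `R/attribution.R` — model classification, traceability, concurrence, TSS
  directionality, proportion standard errors.
- `R/spatial.R` — exon eligibility and cross-platform ΔΨ concordance.
- `R/simulate.R` — the seeded generator and its truth ledger.

The methods vignette (`vignettes/isoform-die-methods.Rmd`) documents the
models, parameter choices, numerical conventions, and the generator's scope
and limitations.
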