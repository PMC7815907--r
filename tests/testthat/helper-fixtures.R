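# Fixtures are built in code: a tiny hand-written annotation/genome pair for
# the I/O and filtering units, and cached seeded simulations for the heavier
# property tests (computed once per test run).

# two-gene annotation on one chromosome; GA and GB share a donor at 200
tiny_gtf_lines <- function() {
  c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1";',
    'chr1\ttest\texon\t301\t400\t.\t+\t.\tgene_id "GA"; transcript_id "GA.t1";',
    'chr1\ttest\texon\t151\t200\t.\t+\t.\tgene_id "GB"; transcript_id "GB.t1";',
    'chr1\ttest\texon\t351\t430\t.\t+\t.\tgene_id "GB"; transcript_id "GB.t1";',
    'chr1\ttest\texon\t601\t700\t.\t+\t.\tgene_id "GC"; transcript_id "GC.t1"; gene_biotype "rRNA";',
    'chr1\ttest\texon\t801\t900\t.\t-\t.\tgene_id "GD"; transcript_id "GD.t1";',
    'chr1\ttest\texon\t1001\t1100\t.\t-\t.\tgene_id "GD"; transcript_id "GD.t1";'
  )
}

tiny_gtf_path <- function() {
  path <- tempfile(fileext = ".gtf")
  writeLines(tiny_gtf_lines(), path)
  path
}

# 1.2 kb genome carrying consensus motifs at the tiny annotation's introns:
# GA intron (200,300) and GB intron (200,350) share the donor; GD (minus
# strand) intron (900,1000) carries CT..AC on the plus strand.
tiny_genome <- function() {
  base <- rep("A", 1200L)
  plant_plus <- function(b, d, a) { b[d + 1:2] <- c("G", "T"); b[a - 1:0] <- c("A", "G"); b }
  base <- plant_plus(base, 200L, 300L)
  base[349:350] <- c("A", "G")                      # GB acceptor at 350
  base[901:902] <- c("C", "T"); base[999:1000] <- c("A", "C")  # GD, minus strand
  structure(setNames(paste(base, collapse = ""), "chr1"), class = "genome_seq")
}

aln_row <- function(read_id, chrom = "chr1", strand = "+", start, end,
                    introns = "", mapq = 60L, barcode = NA_character_) {
  data.table::data.table(read_id = read_id, barcode = barcode, chrom = chrom,
                         strand = strand, start = as.integer(start),
                         end = as.integer(end), introns = introns,
                         mapq = as.integer(mapq))
}

# memoised simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

sim_exact <- function() cached("sim_exact", {
  cfg <- sim_config(n_genes = 10, n_die_genes = 3, die_dpi = 0.3,
                    novel_genes = 2, depth = 100, exact_counts = TRUE)
  sim <- simulate_dataset(cfg, seed = 101)
  pr <- process_reads(sim$reads, sim$genes, sim$genome, sim$cage, sim$polya,
                      sim$cellmap, tolerance = cfg$tolerance)
  list(sim = sim, csmm = pr$csmm, stages = pr$stages)
})

sim_noisy <- function() cached("sim_noisy", {
  cfg <- sim_config(n_genes = 20, n_die_genes = 5, die_dpi = 0.3,
                    novel_genes = 2, depth = 150)
  sim <- simulate_dataset(cfg, seed = 202)
  pr <- process_reads(sim$reads, sim$genes, sim$genome, sim$cage, sim$polya,
                      sim$cellmap, tolerance = cfg$tolerance)
  list(sim = sim, csmm = pr$csmm, stages = pr$stages)
})

# full read-level null study: 1000 genes, depth 100 per group, one leaf type
null_big <- function() cached("null_big", {
  cfg <- sim_config(n_genes = 1000, cell_types = "Cell", depth = 100,
                    truncation_rate = 0, barcodes_per_type = 20)
  sim <- simulate_null(cfg, seed = 606)
  pr <- process_reads(sim$reads, sim$genes, sim$genome, sim$cage, sim$polya,
                      sim$cellmap, tolerance = cfg$tolerance)
  grp <- make_groups(pr$csmm, sim$cellmap,
                     list(node = "bulk", sample = "HIPP", label = "A"),
                     list(node = "bulk", sample = "PFC", label = "B"))
  die_test(pr$csmm, grp)
})

# expected isoform keys per truth isoform
truth_keys <- function(sim) {
  tr <- data.table::as.data.table(sim$truth$isoforms)
  tr[, key := paste(gene_id, tss_peak_id, chain, polya_peak_id, sep = "|")]
  tr
}
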