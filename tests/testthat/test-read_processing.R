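test_that("alignment selection follows the MAPQ and margin rules", {
  one <- aln_row("r1", start = 0, end = 100, mapq = 20)
  expect_equal(nrow(select_alignment(one)), 1L)
  expect_equal(nrow(select_alignment(aln_row("r1", start = 0, end = 100, mapq = 19))), 0L)

  two <- rbind(aln_row("r2", start = 0, end = 100, mapq = 60),
               aln_row("r2", start = 500, end = 600, mapq = 30))
  kept <- select_alignment(two)
  expect_equal(kept$mapq, 60L)

  close <- rbind(aln_row("r3", start = 0, end = 100, mapq = 60),
                 aln_row("r3", start = 500, end = 600, mapq = 50))
  expect_equal(nrow(select_alignment(close)), 0L)
  expect_equal(nrow(select_alignment(close[0])), 0L)
})

test_that("consensus check demands a valid motif at every intron", {
  gs <- load_annotation(tiny_gtf_path())
  genome <- tiny_genome()
  good <- aln_row("r1", start = 150, end = 380, introns = "200-300")
  expect_true(check_consensus(good, genome))

  # same intron read on a genome without motifs fails
  blank <- structure(setNames(strrep("A", 1200), "chr1"), class = "genome_seq")
  expect_false(check_consensus(good, blank))

  # one bad intron disqualifies the whole read
  mixed <- aln_row("r2", start = 150, end = 380, introns = "200-300;320-360")
  expect_false(check_consensus(mixed, genome))

  # minus strand: plus-strand CT..AC reads GT-AG after reverse complement
  minus <- aln_row("r3", strand = "-", start = 850, end = 1050, introns = "900-1000")
  expect_true(check_consensus(minus, genome))

  # unspliced reads fail under spliced-only, pass otherwise
  flat <- aln_row("r4", start = 100, end = 200)
  expect_false(check_consensus(flat, genome))
  expect_true(check_consensus(flat, genome, spliced_only = FALSE))

  # intron beyond chromosome bounds is an error
  oob <- aln_row("r5", start = 100, end = 5000, introns = "200-4000")
  expect_error(check_consensus(oob, genome), "bounds")
})

test_that("gene assignment returns the argmax set of shared splice sites", {
  gs <- load_annotation(tiny_gtf_path())
  # GA intron (200,300): shares donor 200 with GB, acceptor 300 only with GA
  r <- aln_row("r1", start = 150, end = 380, introns = "200-300")
  ga <- assign_gene(r, gs)
  expect_equal(ga$gene_id, "GA")
  expect_false(ga$ambiguous)

  # donor 200 only: tied between GA and GB
  tie <- aln_row("r2", start = 150, end = 380, introns = "200-360")
  gt <- assign_gene(tie, gs)
  expect_setequal(gt$gene_id, c("GA", "GB"))
  expect_true(all(gt$ambiguous))

  # zero shared sites -> absent from the result
  none <- aln_row("r3", start = 150, end = 380, introns = "210-290")
  expect_equal(nrow(assign_gene(none, gs)), 0L)
})

test_that("completeness matching uses boundary distance and 5'/3' tie rules", {
  cage <- structure(data.table::data.table(
    chrom = "chr1", start = c(100L, 201L), end = c(150L, 251L),
    peak_id = c("P1", "P2"), strand = "+"), class = c("peak_set", "data.table", "data.frame"))
  pa <- structure(data.table::data.table(
    chrom = "chr1", start = 900L, end = 950L, peak_id = "Q1", strand = "+"),
    class = c("peak_set", "data.table", "data.frame"))

  # start 160: 10 bp past P1's boundary -> matched
  r <- aln_row("r1", start = 160, end = 930)
  m <- filter_complete(r, cage, pa)
  expect_equal(m$tss_peak_id, "P1")
  expect_equal(m$polya_peak_id, "Q1")

  # start 305: nearest boundary 250 -> gap 55 > 50 -> incomplete
  far <- aln_row("r2", start = 305, end = 930)
  expect_true(is.na(filter_complete(far, cage, pa)$tss_peak_id))

  # equidistant between P1 (upstream) and P2 -> the more 5' peak wins
  mid <- aln_row("r3", start = 175, end = 930)
  expect_equal(filter_complete(mid, cage, pa)$tss_peak_id, "P1")
})

test_that("rRNA overlap drops reads at any overlap, strand-blind", {
  gs <- load_annotation(tiny_gtf_path())   # GC = rRNA at [600, 700)
  inside <- aln_row("r1", start = 620, end = 680)
  onebp <- aln_row("r2", start = 550, end = 601)
  adjacent <- aln_row("r3", start = 550, end = 600)
  minus <- aln_row("r4", strand = "-", start = 650, end = 800)
  expect_equal(drop_rrna(rbind(inside, onebp, adjacent, minus), gs),
               c(TRUE, TRUE, FALSE, TRUE))
})

test_that("deconvolution is exact-match with NA for unknown or missing barcodes", {
  cm <- cell_type_map(data.frame(barcode = "AAAC", cell_type = "EN"),
                      data.frame(parent = "bulk", child = c("EN", "IN")))
  r <- rbind(aln_row("r1", start = 0, end = 10, barcode = "AAAC"),
             aln_row("r2", start = 0, end = 10, barcode = "TTTT"),
             aln_row("r3", start = 0, end = 10))
  expect_equal(deconvolve(r, cm), c("EN", NA, NA))
})

test_that("pipeline stage counts sum to the input and truth genes are recovered", {
  se <- sim_exact()
  st <- se$stages
  expect_equal(sum(st[names(st) != "input"]), unname(st["input"]))
  # zero noise: every read survives and is assigned its source gene
  expect_equal(unname(st["csmm"]), unname(st["input"]))
  tr <- se$sim$truth$reads
  merged <- merge(se$csmm[, c("read_id", "gene_id")], tr[, c("read_id", "gene_id")],
                  by = "read_id", suffixes = c("", "_true"))
  expect_equal(nrow(merged), nrow(se$csmm))
  expect_true(all(merged$gene_id == merged$gene_id_true))
})

test_that("BAM input reproduces the alignment-table path", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  # two spliced reads, one with a CB tag, built as SAM text
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1200",
    paste0("r1\t0\tchr1\t151\t60\t50M100N80M\t*\t0\t0\t",
           strrep("A", 130), "\t*\tCB:Z:AAAC"),
    paste0("r2\t16\tchr1\t851\t60\t50M100N50M\t*\t0\t0\t",
           strrep("A", 100), "\t*")), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  al <- read_alignment_bam(bam)
  al <- al[order(al$read_id)]
  expect_equal(al$read_id, c("r1", "r2"))
  expect_equal(al$barcode, c("AAAC", NA))
  expect_equal(al$start, c(150L, 850L))
  expect_equal(al$introns, c("200-300", "900-1000"))
  expect_equal(al$mapq, c(60L, 60L))
})
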