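make_csmm <- function(n, gene = "G1", tss = "T1", pa = "P1", chain = "",
                      start = 100L, end = 900L, strand = "+") {
  data.table::data.table(read_id = sprintf("r%03d", seq_len(n)), gene_id = gene,
                         chrom = "chr1", strand = strand, start = start, end = end,
                         introns = chain, tss_peak_id = tss, polya_peak_id = pa)
}

test_that("usage tables give exact counts, Pi fractions, and rank tie order", {
  csmm <- rbind(make_csmm(10, chain = "200-300"),            # isoform X
                make_csmm(5, chain = "200-400"))             # isoform Y
  grp <- rep("EN", 15)
  ut <- build_usage_tables(csmm, grp)
  m <- usage_matrix(ut, "G1")
  expect_equal(unname(m[, "EN"]), c(10L, 5L))
  pim <- pi_fractions(m)
  expect_equal(unname(pim[, "EN"]), c(2 / 3, 1 / 3))

  # ranks on summed abundance with ties broken by canonical string order
  csmm2 <- rbind(make_csmm(7, chain = "200-500"), make_csmm(7, chain = "200-300"),
                 make_csmm(3, chain = "200-400"))
  m2 <- usage_matrix(build_usage_tables(csmm2, rep("EN", 17)), "G1")
  expect_equal(rownames(m2)[3], "G1|T1|200-400|P1")
  expect_true(rownames(m2)[1] < rownames(m2)[2])  # tie -> string order
})

test_that("collapse keeps the top 10 rows, sums the rest, preserves column totals", {
  set.seed(9)
  counts <- matrix(rpois(24, 30), ncol = 2,
                   dimnames = list(sprintf("iso%02d", 1:12), c("A", "B")))
  cl <- collapse_top_k(counts, k = 10)
  expect_equal(dim(cl), c(11L, 2L))
  expect_equal(colSums(cl), colSums(counts))
  o <- order(-rowSums(counts), rownames(counts))
  expect_equal(unname(cl["other", ]), unname(colSums(counts[o[11:12], ])))

  small <- counts[1:3, ]
  expect_equal(collapse_top_k(small, k = 10), small)
})

test_that("annotated assignment minimizes end divergence with TSS tie-break", {
  ex <- data.table::data.table(
    transcript_id = rep(c("tA", "tB"), each = 2),
    gene_id = "G1", chrom = "chr1", strand = "+",
    start = c(90L, 500L, 150L, 500L),
    end = c(400L, 2010L, 400L, 2000L))
  gs <- gene_set(ex)
  # both transcripts share the chain (400,500)
  read <- make_csmm(1, chain = "400-500", start = 100L, end = 2000L)
  # A: |100-90| + |2000-2010| = 20 ; B: |100-150| + |2000-2000| = 50
  expect_equal(assign_to_annotated(read, gs), "tA")

  ex2 <- data.table::copy(ex)
  ex2[transcript_id == "tA", start := c(70L, 500L)]   # A: 30 + 10 = 40, TSS diff 30
  ex2[transcript_id == "tB", `:=`(start = c(100L, 500L), end = c(400L, 2040L))] # B: 0 + 40, TSS diff 0
  gs2 <- gene_set(ex2)
  expect_equal(assign_to_annotated(read, gs2), "tB")

  # identical transcripts -> lexicographically smaller id
  ex3 <- data.table::copy(ex)
  ex3[transcript_id == "tB", `:=`(start = c(90L, 500L), end = c(400L, 2010L))]
  gs3 <- gene_set(ex3)
  expect_equal(assign_to_annotated(read, gs3), "tA")

  # no candidate -> NA (novel candidate)
  novel <- make_csmm(1, chain = "400-600", start = 100L, end = 2000L)
  expect_true(is.na(assign_to_annotated(novel, gs)))
})

test_that("novel discovery applies the annotation rules in order", {
  ex <- data.table::data.table(
    transcript_id = "t1", gene_id = "G1", chrom = "chr1", strand = "+",
    start = c(100L, 300L, 500L, 700L), end = c(200L, 400L, 600L, 800L))
  gs <- gene_set(ex)   # annotated chain: 200-300;400-500;600-700
  sr <- data.table::data.table(
    chrom = "chr1", start = c(200L, 400L, 600L, 200L, 400L),
    end = c(300L, 500L, 700L, 500L, 700L),
    strand = "+", count = c(10L, 10L, 10L, 5L, 1L))

  csmm <- rbind(
    make_csmm(4, chain = "400-500;600-700", end = 800L),   # truncation of annotated
    make_csmm(5, chain = "200-500;600-700", end = 800L),   # novel, supported
    make_csmm(3, chain = "200-500", end = 800L),           # truncation of the novel
    make_csmm(2, chain = "400-700", end = 800L))           # intron support 1
  nv <- discover_novel(csmm, gs, sr)
  nv <- nv[order(chain)]
  get <- function(ch) nv[chain == ch]
  expect_false(get("400-500;600-700")$accepted)
  expect_equal(get("400-500;600-700")$reason, "rule3_annotated_or_truncation")
  expect_true(get("200-500;600-700")$accepted)
  expect_false(get("200-500")$accepted)
  expect_equal(get("200-500")$reason, "rule6_truncation_of_novel")
  expect_false(get("400-700")$accepted)
  expect_equal(get("400-700")$reason, "rule5_intron_support")
})

test_that("internal exon support rule fires when a flanking junction is weak", {
  ex <- data.table::data.table(
    transcript_id = "t1", gene_id = "G1", chrom = "chr1", strand = "+",
    start = c(100L, 300L, 500L, 700L), end = c(200L, 400L, 600L, 800L))
  gs <- gene_set(ex)
  # novel chain with middle intron support 1: exon between introns 1 and 2
  sr <- data.table::data.table(chrom = "chr1", start = c(200L, 420L, 600L),
                               end = c(300L, 500L, 700L), strand = "+",
                               count = c(10L, 1L, 10L))
  csmm <- make_csmm(3, chain = "200-300;420-500;600-700", end = 800L)
  nv <- discover_novel(csmm, gs, sr)
  expect_equal(nv$reason, "rule4_internal_exon_support")
})

test_that("enhanced annotation round-trips accepted chains and counts", {
  ex <- data.table::data.table(
    transcript_id = "t1", gene_id = "G1", chrom = "chr1", strand = "+",
    start = c(100L, 300L, 500L, 700L), end = c(200L, 400L, 600L, 800L))
  gs <- gene_set(ex)
  sr <- data.table::data.table(chrom = "chr1", start = c(200L, 600L),
                               end = c(500L, 700L), strand = "+", count = c(3L, 9L))
  csmm <- make_csmm(6, chain = "200-500;600-700", end = 800L)
  grp <- rep(c("P7Hipp_OPCs", "P7PFC_OPCs"), 3)
  nv <- discover_novel(csmm, gs, sr)
  gtf <- tempfile(fileext = ".gtf"); cts <- tempfile(fileext = ".tsv")
  out <- write_enhanced_annotation(nv, gs, csmm, grp, gtf, cts)
  gs2 <- load_annotation(gtf)
  novel_tx <- setdiff(gs2$transcripts$transcript_id, gs$transcripts$transcript_id)
  expect_length(novel_tx, 1L)
  expect_equal(unname(gs2$chains[novel_tx]), "200-500;600-700")
  counts <- read.delim(cts)
  expect_equal(counts$P7Hipp_OPCs, 3L)
  expect_equal(counts$P7PFC_OPCs, 3L)

  # nothing accepted -> annotation body unchanged
  gtf0 <- tempfile(); base <- tempfile()
  export_annotation(gs, base)
  write_enhanced_annotation(nv[0], gs, csmm[0], character(0), gtf0, tempfile())
  expect_equal(grep("^#", readLines(gtf0), value = TRUE, invert = TRUE),
               readLines(base))
})

test_that("planted novel isoforms are recovered with correct rule codes", {
  se <- sim_exact()
  nv <- discover_novel(se$csmm, se$sim$genes, se$sim$sr_junctions)
  truth <- se$sim$truth$novel
  m <- merge(nv, truth, by = c("gene_id", "chain"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$accepted, m$expected_accept)
  expect_equal(m$reason[!m$accepted], m$expected_rule[!m$accepted])
  # everything else rejected as annotated/truncation
  rest <- nv[!truth, on = c("gene_id", "chain")]
  expect_true(all(rest$reason == "rule3_annotated_or_truncation"))
})
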