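# From raw spliced long-read alignments to filtered, gene-assigned,
# cell-type-labelled CSMMs (consensus-split-mapped molecules).
#
# Alignment tables hold one alignment per row:
#   read_id, barcode, chrom, strand, start, end, introns, mapq
# with `introns` the canonical chain string (see chain_string), coordinates
# 0-based half-open, and optional extra columns (e.g. `sample`) passed through.

#' Read an alignment table from TSV
#'
#' @param path TSV with header columns `read_id, barcode, chrom, strand,
#'   start, end, introns, mapq` (extra columns are kept). Missing barcodes may
#'   be `""` or `"."`; unspliced reads have `introns` `""` or `"."`.
#' @return data.table of alignments.
#' @export
read_alignment_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("read_id", "barcode", "chrom", "strand", "introns")))
  need <- c("read_id", "barcode", "chrom", "strand", "start", "end", "introns", "mapq")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("alignment table lacks columns: ", paste(miss, collapse = ", "))
  dt[introns == ".", introns := ""]
  dt[barcode %in% c(".", ""), barcode := NA_character_]
  dt[, `:=`(start = as.integer(start), end = as.integer(end), mapq = as.integer(mapq))]
  dt[]
}

#' Read spliced alignments from BAM
#'
#' Extracts one row per alignment with the intron chain derived from the
#' CIGAR N operations and the cell barcode from a tag (default `CB`).
#'
#' @param path BAM path (indexed not required).
#' @param barcode_tag SAM tag holding the corrected cell barcode.
#' @return data.table in the [read_alignment_table()] schema.
#' @export
read_alignment_bam <- function(path, barcode_tag = "CB") {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("BAM input requires Rsamtools and GenomicAlignments")
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq"), tag = barcode_tag,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  jl <- GenomicAlignments::junctions(ga)
  chains <- vapply(seq_along(jl), function(i) {
    j <- jl[[i]]
    if (length(j) == 0L) return("")
    chain_string(GenomicRanges::start(j) - 1L, GenomicRanges::end(j))
  }, character(1))
  md <- S4Vectors::mcols(ga)
  bc <- if (barcode_tag %in% names(md)) as.character(md[[barcode_tag]]) else NA_character_
  data.table(
    read_id = as.character(md$qname),
    barcode = bc,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(GenomicAlignments::strand(ga)),
    start = GenomicRanges::start(ga) - 1L,
    end = GenomicRanges::end(ga),
    introns = chains,
    mapq = as.integer(md$mapq))
}

#' Select one alignment per read by mapping quality
#'
#' A read's unique alignment is kept if its MAPQ is at least `min_mapq`; with
#' multiple alignments, the best is kept only if its MAPQ exceeds the maximum
#' of all the others by at least `min_margin`. Otherwise the read is dropped.
#'
#' @param alignments alignment table (possibly several rows per `read_id`).
#' @param min_mapq minimum MAPQ for a uniquely aligned read (default 20).
#' @param min_margin required MAPQ margin over the runner-up (default 20).
#' @return alignment table with one row per surviving read.
#' @export
select_alignment <- function(alignments, min_mapq = 20L, min_margin = 20L) {
  al <- as.data.table(alignments)
  if (nrow(al) == 0L) return(al)
  al[, n_aln := .N, by = read_id]
  keep1 <- al[n_aln == 1L & mapq >= min_mapq]
  multi <- al[n_aln > 1L]
  if (nrow(multi)) {
    setorder(multi, read_id, -mapq)
    multi[, second := mapq[2L], by = read_id]
    keep2 <- multi[, .SD[1L], by = read_id][mapq - second >= min_margin]
    keep2[, second := NULL]
    out <- rbind(keep1, keep2)
  } else out <- keep1
  out[, n_aln := NULL]
  out[]
}

#' Snap junction coordinates to nearby annotated splice sites
#'
#' Aligners place most splice junctions exactly on annotated sites, but
#' platform-specific alignment error can shift a junction by a few bases.
#' Each donor (acceptor) within `tolerance` bp of an annotated donor
#' (acceptor) on the same chromosome and strand is moved onto it; junctions
#' with no annotated site within tolerance are left untouched (candidate
#' novel junctions).
#'
#' @param reads alignment table.
#' @param genes a `gene_set`.
#' @param tolerance snap distance in bp: 2 for PacBio, 3 for ONT.
#' @return the alignment table with `introns` rewritten.
#' @export
snap_junctions <- function(reads, genes, tolerance = 2L) {
  reads <- as.data.table(reads)
  long <- chains_to_long(reads$introns)
  if (nrow(long) == 0L) return(reads[])
  long[, `:=`(chrom = reads$chrom[read_idx], strand = reads$strand[read_idx])]
  for (side in c("donor", "acceptor")) {
    ann <- unique(genes$splice_sites[site == side, .(chrom, strand, coord)])
    if (nrow(ann) == 0L) next
    setkey(ann, chrom, strand, coord)
    q <- long[, .(chrom, strand, coord = get(side))]
    idx <- ann[q, which = TRUE, roll = "nearest", on = c("chrom", "strand", "coord")]
    matched <- ifelse(is.na(idx), NA_integer_, ann$coord[idx])
    ok <- !is.na(matched) & abs(matched - long[[side]]) <= tolerance
    long[ok, (side) := matched[ok]]
  }
  long <- long[donor < acceptor]           # guard against degenerate snaps
  reads[, introns := long_to_chains(long[, .(read_idx, donor, acceptor)], nrow(reads))]
  reads[]
}

#' Check splice-motif consensus per read
#'
#' A read passes iff every intron's strand-corrected dinucleotides form one of
#' the GT-AG, GC-AG or AT-AC consensus motifs. Unspliced reads return `FALSE`
#' when `spliced_only = TRUE` (the default pipeline analyses spliced
#' molecules only), otherwise `TRUE`.
#'
#' @param reads alignment table.
#' @param genome a `genome_seq` (named chromosome sequences).
#' @param spliced_only treat unspliced reads as failing.
#' @return logical vector, one element per read.
#' @export
check_consensus <- function(reads, genome, spliced_only = TRUE) {
  reads <- as.data.table(reads)
  long <- chains_to_long(reads$introns)
  ok <- rep(!spliced_only, nrow(reads))
  spliced <- unique(long$read_idx)
  if (length(spliced) == 0L) return(ok)
  long[, `:=`(chrom = reads$chrom[read_idx], strand = reads$strand[read_idx])]
  bad_chrom <- setdiff(unique(long$chrom), names(genome))
  if (length(bad_chrom)) stop("chromosome absent from genome: ", bad_chrom[1])
  clen <- nchar(genome)[long$chrom]
  if (any(long$donor < 0L | long$acceptor > clen)) {
    stop("intron outside chromosome bounds")
  }
  seqs <- unclass(genome)[long$chrom]
  first2 <- toupper(substr(seqs, long$donor + 1L, long$donor + 2L))
  last2 <- toupper(substr(seqs, long$acceptor - 1L, long$acceptor))
  plus <- long$strand != "-"
  motif <- character(nrow(long))
  motif[plus] <- paste0(first2[plus], last2[plus])
  if (any(!plus)) {
    motif[!plus] <- paste0(revcomp(last2[!plus]), revcomp(first2[!plus]))
  }
  good <- motif %in% c("GTAG", "GCAG", "ATAC")
  agg <- tapply(good, long$read_idx, all)
  ok[as.integer(names(agg))] <- as.logical(agg)
  ok
}

#' Assign reads to genes by shared splice sites
#'
#' Counts, per read, how many of its splice-site coordinates occur in the
#' annotation's splice-site index for each gene, and returns the argmax gene
#' set (all tied genes).
#'
#' @param reads alignment table.
#' @param genes a `gene_set`.
#' @return data.table with columns `read_idx`, `gene_id`, `n_shared`,
#'   `ambiguous`; reads sharing zero annotated sites are absent.
#' @export
assign_gene <- function(reads, genes) {
  reads <- as.data.table(reads)
  long <- chains_to_long(reads$introns)
  empty <- data.table(read_idx = integer(0), gene_id = character(0),
                      n_shared = integer(0), ambiguous = logical(0))
  if (nrow(long) == 0L) return(empty)
  long[, `:=`(chrom = reads$chrom[read_idx], strand = reads$strand[read_idx])]
  qs <- rbind(long[, .(read_idx, chrom, strand, coord = donor)],
              long[, .(read_idx, chrom, strand, coord = acceptor)])
  hits <- genes$splice_sites[qs, on = c("chrom", "strand", "coord"),
                             nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty)
  cnt <- unique(hits[, .(read_idx, gene_id, coord)])[, .(n_shared = .N),
                                                     by = .(read_idx, gene_id)]
  cnt[, best := max(n_shared), by = read_idx]
  out <- cnt[n_shared == best][, best := NULL]
  out[, ambiguous := .N > 1L, by = read_idx]
  setorder(out, read_idx, gene_id)
  out[]
}

#' Match read ends to CAGE and polyA peaks
#'
#' The biological 5' end of a read (its start on `+`, its end on `-`) must lie
#' within `window` bp of a CAGE peak and the 3' end within `window` bp of a
#' polyA peak for the read to be called complete (full-length). Distance to a
#' peak is 0 inside the interval and the gap to the nearest boundary outside.
#' Among equally near peaks the more 5' peak wins for the TSS and the more 3'
#' peak for the polyA site (strand-aware).
#'
#' @param reads alignment table (strand column used for end polarity).
#' @param cage,polya `peak_set`s.
#' @param window maximum gap in bp (default 50).
#' @return data.table with columns `tss_peak_id`, `polya_peak_id` (`NA` when
#'   no peak is within the window).
#' @export
filter_complete <- function(reads, cage, polya, window = 50L) {
  reads <- as.data.table(reads)
  minus <- reads$strand == "-"
  five <- ifelse(minus, reads$end - 1L, reads$start)
  three <- ifelse(minus, reads$start, reads$end - 1L)
  data.table(
    tss_peak_id = match_peak(reads$chrom, reads$strand, five, cage, window, tss = TRUE),
    polya_peak_id = match_peak(reads$chrom, reads$strand, three, polya, window, tss = FALSE))
}

# nearest strand-matched peak within window; tie -> most 5' (tss) / most 3'.
# The gap to a peak [ps, pe) from a coordinate c is 0 inside the interval,
# c - pe downstream, and ps - c - 1 upstream (bases strictly between).
match_peak <- function(chrom, strand, coord, peaks, window, tss) {
  n <- length(coord)
  out <- rep(NA_character_, n)
  if (nrow(peaks) == 0L || n == 0L) return(out)
  pts <- GenomicRanges::GRanges(chrom, IRanges::IRanges(coord + 1L, width = 1L),
                                strand = strand)
  pgr <- GenomicRanges::GRanges(peaks$chrom,
                                IRanges::IRanges(peaks$start + 1L, peaks$end),
                                strand = peaks$strand)
  hits <- GenomicRanges::findOverlaps(pts, pgr, maxgap = window,
                                      ignore.strand = FALSE)
  if (length(hits) == 0L) return(out)
  ht <- data.table(q = S4Vectors::queryHits(hits),
                   s = S4Vectors::subjectHits(hits))
  cc <- coord[ht$q]; ps <- peaks$start[ht$s]; pe <- peaks$end[ht$s]
  ht[, gap := fifelse(cc >= pe, cc - pe, fifelse(cc < ps, ps - cc - 1L, 0L))]
  ht <- ht[gap <= window]
  if (nrow(ht) == 0L) return(out)
  # tie-break position: 5' end of the peak in transcription orientation
  minus <- strand[ht$q] == "-"
  tie_pos <- ifelse(minus, -(peaks$end[ht$s]), peaks$start[ht$s])
  if (!tss) tie_pos <- -tie_pos               # 3'-most instead
  ht[, pos := tie_pos]
  setorder(ht, q, gap, pos)
  best <- ht[, .SD[1L], by = q]
  out[best$q] <- peaks$peak_id[best$s]
  out
}

#' Flag reads overlapping annotated rRNA genes
#'
#' @param reads alignment table.
#' @param genes a `gene_set`.
#' @return logical vector: `TRUE` means drop (any overlap with an rRNA gene
#'   span, on either strand).
#' @export
drop_rrna <- function(reads, genes) {
  reads <- as.data.table(reads)
  rr <- genes$genes[rrna == TRUE]
  if (nrow(rr) == 0L || nrow(reads) == 0L) return(rep(FALSE, nrow(reads)))
  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$start + 1L, reads$end))
  gr <- GenomicRanges::GRanges(rr$chrom, IRanges::IRanges(rr$start + 1L, rr$end))
  IRanges::overlapsAny(rgr, gr, ignore.strand = TRUE)
}

#' Map barcodes to cell types
#'
#' Exact-match lookup; reads with a missing barcode or a barcode absent from
#' the map get `NA` (they stay in bulk-level analyses only).
#'
#' @param reads alignment table.
#' @param cellmap a `cell_type_map`.
#' @return character vector of leaf cell types (or `NA`).
#' @export
deconvolve <- function(reads, cellmap) {
  reads <- as.data.table(reads)
  unname(cellmap$map[reads$barcode])
}

#' Run the full CSMM filter pipeline
#'
#' Fixed, composable stage order: alignment selection by MAPQ, rRNA removal,
#' junction snapping, splice-motif consensus, gene assignment by shared splice
#' sites, completeness against CAGE/polyA peaks, barcode deconvolution.
#'
#' @param reads alignment table (one or more alignments per read).
#' @param genes a `gene_set`.
#' @param genome a `genome_seq`.
#' @param cage,polya `peak_set`s.
#' @param cellmap optional `cell_type_map` (without it `cell_type` is `NA`).
#' @param window CAGE/polyA matching window in bp.
#' @param tolerance junction snap tolerance in bp (2 PacBio, 3 ONT).
#' @param spliced_only drop unspliced reads (default `TRUE`).
#' @param drop_ambiguous drop reads tied between several genes (default
#'   `TRUE`, avoiding double counting in the statistics; set `FALSE` to count
#'   a tied read once per gene, flagged `ambiguous`).
#' @param require_complete keep only reads with both peak matches (default
#'   `TRUE`).
#' @param snap apply [snap_junctions()] (default `TRUE`).
#' @return list with `csmm` (the CSMM table: alignment columns plus `gene_id`,
#'   `ambiguous`, `tss_peak_id`, `polya_peak_id`, `cell_type`) and `stages`, a
#'   named integer vector of reads dropped per stage plus the surviving count;
#'   its elements sum to the number of distinct input reads.
#' @export
process_reads <- function(reads, genes, genome, cage, polya, cellmap = NULL,
                          window = 50L, tolerance = 2L, spliced_only = TRUE,
                          drop_ambiguous = TRUE, require_complete = TRUE,
                          snap = TRUE) {
  reads <- as.data.table(reads)
  n_input <- length(unique(reads$read_id))
  stages <- c(input = n_input)

  al <- select_alignment(reads)
  stages["mapq_filtered"] <- n_input - nrow(al)

  rr <- drop_rrna(al, genes)
  al <- al[!rr]
  stages["rrna_overlap"] <- sum(rr)

  if (snap) al <- snap_junctions(al, genes, tolerance)

  cons <- check_consensus(al, genome, spliced_only = spliced_only)
  al <- al[cons]
  stages["non_consensus"] <- sum(!cons)

  ga <- assign_gene(al, genes)
  if (drop_ambiguous) ga <- ga[ambiguous == FALSE]
  assigned_reads <- unique(ga$read_idx)
  stages["no_gene"] <- nrow(al) - length(assigned_reads)
  al <- al[assigned_reads]
  ga[, read_idx := match(read_idx, assigned_reads)]

  # strand of a read follows its assigned gene
  gene_strand <- setNames(genes$genes$strand, genes$genes$gene_id)
  # one row per (read, gene); unambiguous default means one row per read
  csmm <- al[ga$read_idx]
  csmm[, `:=`(gene_id = ga$gene_id, ambiguous = ga$ambiguous)]
  csmm[, strand := gene_strand[gene_id]]

  pk <- filter_complete(csmm, cage, polya, window)
  csmm[, `:=`(tss_peak_id = pk$tss_peak_id, polya_peak_id = pk$polya_peak_id)]
  if (require_complete) {
    complete <- !is.na(csmm$tss_peak_id) & !is.na(csmm$polya_peak_id)
    n_before <- length(unique(csmm$read_id))
    csmm <- csmm[complete]
    stages["incomplete"] <- n_before - length(unique(csmm$read_id))
  } else stages["incomplete"] <- 0L
  csmm[, cell_type := if (is.null(cellmap)) NA_character_ else deconvolve(csmm, cellmap)]
  stages["csmm"] <- length(unique(csmm$read_id))
  list(csmm = csmm[], stages = stages)
}
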