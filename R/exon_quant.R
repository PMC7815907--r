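# Per-read exon inclusion/exclusion calls with platform-specific junction
# tolerance, and percent-spliced-in (Psi) tables per cell group.

#' Distinct annotated exons with terminal and overlap flags
#'
#' One row per distinct exon interval per gene. An exon is flagged `terminal`
#' when it is the first or last exon of every transcript containing it
#' (terminal exons are judged by coverage, not junctions). It is flagged
#' `overlapping` when a different annotated exon interval overlaps it (used by
#' the spatial eligibility filter; such exons have alternative donors or
#' acceptors).
#'
#' @param genes a `gene_set`.
#' @return data.table: `exon_id, gene_id, chrom, strand, start, end, terminal,
#'   overlapping`.
#' @export
exon_catalog <- function(genes) {
  ex <- copy(genes$exons)
  ex[, terminal := exon_rank == 1L | exon_rank == max(exon_rank), by = transcript_id]
  cat <- ex[, .(terminal = all(terminal)), by = .(gene_id, chrom, strand, start, end)]
  cat[, exon_id := sprintf("%s:%s:%d-%d", gene_id, chrom, start, end)]
  gr <- GenomicRanges::GRanges(cat$chrom, IRanges::IRanges(cat$start + 1L, cat$end))
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  ht <- data.table(q = S4Vectors::queryHits(hits), s = S4Vectors::subjectHits(hits))
  ht <- ht[q != s]
  # overlap with an exon of different boundaries counts; identical intervals
  # shared across genes do not make an exon ambiguous by themselves
  ht <- ht[cat$start[q] != cat$start[s] | cat$end[q] != cat$end[s]]
  cat[, overlapping := FALSE]
  cat[unique(ht$q), overlapping := TRUE]
  setcolorder(cat, c("exon_id", "gene_id", "chrom", "strand", "start", "end",
                     "terminal", "overlapping"))
  cat[]
}

#' Call exon inclusion per read
#'
#' For every (read, exon-of-the-read's-gene) pair whose intervals overlap:
#'
#' * internal exon: `included` when the read has an intron ending within
#'   `tolerance` bp of the exon's start (acceptor) and an intron starting
#'   within `tolerance` bp of the exon's end (donor); otherwise `excluded`
#'   when the alignment spans the whole exon without those junctions;
#'   otherwise `discarded` (read ends inside the exon).
#' * terminal exon: `included` only when completely covered by read exonic
#'   sequence; `excluded` when a read intron contains it; partial coverage is
#'   `discarded`.
#'
#' @param csmm CSMM table (gene-assigned reads).
#' @param genes a `gene_set`.
#' @param tolerance junction tolerance in bp: 2 for PacBio, 3 for ONT.
#' @param catalog optional precomputed [exon_catalog()].
#' @return data.table of calls: `exon_id, gene_id, read_idx, read_id, status,
#'   terminal, overlapping` with `status` in included/excluded/discarded.
#' @export
call_exons <- function(csmm, genes, tolerance = 2L, catalog = NULL) {
  csmm <- as.data.table(csmm)
  cat <- as.data.table(catalog %||% exon_catalog(genes))
  rd <- data.table(read_idx = seq_len(nrow(csmm)), gene_id = csmm$gene_id,
                   rstart = csmm$start, rend = csmm$end, read_id = csmm$read_id)
  P <- cat[rd, on = "gene_id", nomatch = NULL, allow.cartesian = TRUE]
  P <- P[rstart < end & rend > start]                 # reads overlapping the locus
  if (nrow(P) == 0L) {
    return(data.table(exon_id = character(0), gene_id = character(0),
                      read_idx = integer(0), read_id = character(0),
                      status = character(0), terminal = logical(0),
                      overlapping = logical(0)))
  }
  setnames(P, c("start", "end"), c("es", "ee"))
  P[, `:=`(es_lo = es - tolerance, es_hi = es + tolerance,
           ee_lo = ee - tolerance, ee_hi = ee + tolerance)]
  J <- chains_to_long(csmm$introns)

  first_hit <- function(on_expr) {
    if (nrow(J) == 0L) return(rep(FALSE, nrow(P)))
    !is.na(J[P, on = on_expr, mult = "first", which = TRUE])
  }
  match_a <- first_hit(c("read_idx", "acceptor>=es_lo", "acceptor<=es_hi"))
  match_d <- first_hit(c("read_idx", "donor>=ee_lo", "donor<=ee_hi"))
  contained <- first_hit(c("read_idx", "donor<=es", "acceptor>=ee"))
  intron_overlap <- first_hit(c("read_idx", "donor<ee", "acceptor>es"))
  spans <- P$rstart <= P$es & P$rend >= P$ee

  status <- rep("discarded", nrow(P))
  internal <- !P$terminal
  status[internal & match_a & match_d] <- "included"
  status[internal & !(match_a & match_d) & spans] <- "excluded"
  covered <- spans & !intron_overlap
  status[!internal & covered] <- "included"
  status[!internal & !covered & contained] <- "excluded"

  P[, status := status]
  P[, .(exon_id, gene_id, read_idx, read_id, status, terminal, overlapping)]
}

#' Aggregate exon calls to Psi tables per cell group
#'
#' @param calls result of [call_exons()].
#' @param group cell-group labels aligned with the CSMM table the calls were
#'   made from (indexed by `calls$read_idx`); `NA` rows are dropped.
#' @return a `psi_table`: data.table `exon_id, group, incl, excl, psi` with
#'   `psi = incl / (incl + excl)` (NaN when no informative reads).
#' @export
psi_tables <- function(calls, group) {
  calls <- as.data.table(calls)
  calls[, group := as.character(group[read_idx])]
  calls <- calls[!is.na(group)]
  pt <- calls[, .(incl = sum(status == "included"),
                  excl = sum(status == "excluded")), by = .(exon_id, group)]
  pt[, psi := incl / (incl + excl)]
  setattr(pt, "class", c("psi_table", class(pt)))
  pt[]
}

#' Delta-Psi between two groups
#'
#' @param psi a `psi_table`.
#' @param group_a,group_b group labels; `dpsi = psi_A - psi_B`.
#' @return data.table `exon_id, psi_a, psi_b, dpsi, incl_a, excl_a, incl_b,
#'   excl_b` for exons informative in both groups.
#' @export
delta_psi <- function(psi, group_a, group_b) {
  psi <- as.data.table(psi)
  a <- psi[group == group_a, .(exon_id, psi_a = psi, incl_a = incl, excl_a = excl)]
  b <- psi[group == group_b, .(exon_id, psi_b = psi, incl_b = incl, excl_b = excl)]
  m <- merge(a, b, by = "exon_id")
  m[, dpsi := psi_a - psi_b]
  m[]
}
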