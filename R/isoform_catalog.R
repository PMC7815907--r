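# Isoform identities and per-cell-group count tables; assignment of reads to
# annotated transcripts; novel-isoform discovery under the enhanced-annotation
# rules.
#
# An isoform is identified by the string "gene|tss|d1-a1;d2-a2;...|polyA":
# the matched CAGE peak id, the intron chain, and the matched polyA peak id.
# Using peak ids (rather than raw read ends) keeps end wobble from
# fragmenting isoforms; `key_mode = "raw"` switches to raw end coordinates.

#' Isoform key strings for CSMMs
#'
#' @param csmm CSMM table.
#' @param feature `"isoform"` (full key), `"tss"` (CAGE peak only) or
#'   `"polya"` (polyA peak only).
#' @param key_mode `"peaks"` (default) or `"raw"` (raw end coordinates in
#'   place of peak ids).
#' @return character vector of keys.
#' @export
isoform_key <- function(csmm, feature = c("isoform", "tss", "polya"),
                        key_mode = c("peaks", "raw")) {
  feature <- match.arg(feature)
  key_mode <- match.arg(key_mode)
  csmm <- as.data.table(csmm)
  minus <- csmm$strand == "-"
  tss <- if (key_mode == "peaks") csmm$tss_peak_id else
    as.character(ifelse(minus, csmm$end - 1L, csmm$start))
  pa <- if (key_mode == "peaks") csmm$polya_peak_id else
    as.character(ifelse(minus, csmm$start, csmm$end - 1L))
  switch(feature,
         isoform = paste(csmm$gene_id, tss, csmm$introns, pa, sep = "|"),
         tss = paste(csmm$gene_id, tss, sep = "|"),
         polya = paste(csmm$gene_id, pa, sep = "|"))
}

#' Per-gene isoform usage tables
#'
#' Counts reads per (gene, isoform key, cell group). Isoform ranks within a
#' gene are assigned on abundance summed over all groups, lower rank = higher
#' abundance, ties broken by the canonical key string order.
#'
#' @param csmm CSMM table.
#' @param group character vector aligned with `csmm` rows giving each read's
#'   cell group; rows with `NA` are dropped.
#' @param feature,key_mode see [isoform_key()].
#' @return a `usage_tables` object: data.table with columns `gene_id`, `key`,
#'   `group`, `count` (attribute `feature`).
#' @export
build_usage_tables <- function(csmm, group, feature = "isoform",
                               key_mode = "peaks") {
  csmm <- as.data.table(csmm)
  stopifnot(length(group) == nrow(csmm))
  keep <- !is.na(group)
  ut <- data.table(gene_id = csmm$gene_id[keep],
                   group = as.character(group[keep]))
  ut[, key := isoform_key(csmm[keep], feature, key_mode)]
  ut <- ut[, .(count = .N), by = .(gene_id, key, group)]
  setattr(ut, "feature", feature)
  setattr(ut, "class", c("usage_tables", class(ut)))
  ut[]
}

#' Count matrix of one gene's usage table
#'
#' @param ut a `usage_tables` object.
#' @param gene a gene id present in `ut`.
#' @param groups optional group (column) order; defaults to sorted groups.
#' @return integer matrix, isoform keys as rows in rank order (most abundant
#'   first, ties by key string), groups as columns.
#' @export
usage_matrix <- function(ut, gene, groups = NULL) {
  sub <- as.data.table(ut)[gene_id == gene]
  if (nrow(sub) == 0L) stop("gene not present in usage tables: ", gene)
  groups <- groups %||% sort(unique(sub$group))
  keys <- sub[, .(total = sum(count)), by = key][order(-total, key), key]
  m <- matrix(0L, nrow = length(keys), ncol = length(groups),
              dimnames = list(keys, groups))
  sub <- sub[group %in% groups]
  m[cbind(match(sub$key, keys), match(sub$group, groups))] <- sub$count
  m
}

#' Percent isoform (Pi) per group
#'
#' @param counts isoform x group count matrix.
#' @return matrix of column-wise proportions; columns with zero total are NaN.
#' @export
pi_fractions <- function(counts) {
  sweep(counts, 2L, colSums(counts), "/")
}

#' Collapse a usage matrix to its top-k rows plus a rest row
#'
#' Rows are ranked by total count over both groups (ties by row-name order);
#' the first `k` are kept and the remainder summed into a final `"other"` row,
#' omitted when the gene has `<= k` isoforms. Column sums are preserved.
#'
#' @param counts isoform x 2 count matrix.
#' @param k maximum number of individual isoform rows (default 10, giving at
#'   most a (k+1) x 2 matrix).
#' @return integer matrix with at most `k + 1` rows.
#' @export
collapse_top_k <- function(counts, k = 10L) {
  stopifnot(ncol(counts) == 2L)
  if (nrow(counts) <= k) return(counts)
  o <- order(-rowSums(counts), rownames(counts))
  top <- counts[o[seq_len(k)], , drop = FALSE]
  rest <- colSums(counts[o[-seq_len(k)], , drop = FALSE])
  rbind(top, other = rest)
}

#' Assign CSMMs to annotated transcripts by intron chain and end divergence
#'
#' Candidate transcripts are those of the read's gene whose intron chain
#' equals the read's chain exactly. Among candidates the assignment minimizes
#' `|read start - transcript start| + |read end - transcript end|`; ties are
#' broken by TSS divergence alone, residual ties by transcript id.
#'
#' @param csmm CSMM table.
#' @param genes a `gene_set`.
#' @return character vector of transcript ids (`NA` = no candidate; the read
#'   is a novel-isoform candidate).
#' @export
assign_to_annotated <- function(csmm, genes) {
  csmm <- as.data.table(csmm)
  tx <- copy(genes$transcripts)
  tx[, chain := genes$chains[transcript_id]]
  q <- data.table(read_idx = seq_len(nrow(csmm)), gene_id = csmm$gene_id,
                  chain = csmm$introns, rstart = csmm$start, rend = csmm$end,
                  strand = csmm$strand)
  cand <- tx[q, on = c("gene_id", "chain"), nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0L) return(rep(NA_character_, nrow(csmm)))
  cand[, cost := abs(rstart - start) + abs(rend - end)]
  # TSS divergence is strand-aware: the 5' end of both read and transcript
  cand[, tss_div := ifelse(strand == "-", abs(rend - end), abs(rstart - start))]
  setorder(cand, read_idx, cost, tss_div, transcript_id)
  best <- cand[, .SD[1L], by = read_idx]
  out <- rep(NA_character_, nrow(csmm))
  out[best$read_idx] <- best$transcript_id
  out
}

# is chain `a` (vector of "d-a" tokens) a contiguous subsequence of chain `b`?
is_contiguous_sub <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na > nb) return(FALSE)
  if (na == 0L) return(TRUE)
  for (s in 0:(nb - na)) if (all(a == b[s + seq_len(na)])) return(TRUE)
  FALSE
}

chain_tokens <- function(chain) {
  if (is.na(chain) || chain == "") return(character(0))
  strsplit(chain, ";", fixed = TRUE)[[1]]
}

#' Discover novel isoforms under the enhanced-annotation rules
#'
#' Operates on complete (CAGE- and polyA-matched), spliced, gene-assigned
#' CSMMs, i.e. completeness rules are already enforced upstream. Remaining
#' rules, applied in order with the first failure recorded:
#'
#' * `rule3_annotated_or_truncation`: the intron chain equals, or is a
#'   contiguous subsequence of, an annotated transcript's chain.
#' * `rule4_internal_exon_support`: some internal exon (both flanking
#'   junctions) lacks `min_support` short-read junction records.
#' * `rule5_intron_support`: some intron is supported by fewer than
#'   `min_support` spliced short reads.
#' * `rule6_truncation_of_novel`: the chain is a contiguous proper
#'   subsequence of another surviving novel chain (the longest is kept).
#'
#' @param csmm CSMM table (rows lacking peak matches or introns are ignored).
#' @param genes a `gene_set`.
#' @param sr_junctions junction support table (see [load_junction_support()]).
#' @param min_support minimum spliced short reads per junction (default 2).
#' @param min_reads minimum long reads observing the chain (default 1).
#' @return data.table, one row per candidate (gene, chain): `gene_id`,
#'   `chain`, `n_reads`, `rep_start`, `rep_end` (modal read ends), `accepted`,
#'   `reason` (`""` when accepted).
#' @export
discover_novel <- function(csmm, genes, sr_junctions, min_support = 2L,
                           min_reads = 1L) {
  csmm <- as.data.table(csmm)
  csmm <- csmm[!is.na(tss_peak_id) & !is.na(polya_peak_id) & introns != ""]
  out_empty <- data.table(gene_id = character(0), chain = character(0),
                          n_reads = integer(0), rep_start = integer(0),
                          rep_end = integer(0), accepted = logical(0),
                          reason = character(0))
  if (nrow(csmm) == 0L) return(out_empty)
  cand <- csmm[, .(n_reads = .N,
                   rep_start = as.integer(names(sort(-table(start)))[1]),
                   rep_end = as.integer(names(sort(-table(end)))[1]),
                   chrom = chrom[1L], strand = strand[1L]),
               by = .(gene_id, chain = introns)]
  cand <- cand[n_reads >= min_reads]
  cand[, `:=`(accepted = FALSE, reason = "")]

  ann_by_gene <- split(unname(genes$chains[genes$transcripts$transcript_id]),
                       genes$transcripts$gene_id)
  sr <- as.data.table(sr_junctions)

  toks <- lapply(cand$chain, chain_tokens)
  for (i in seq_len(nrow(cand))) {
    ann <- lapply(ann_by_gene[[cand$gene_id[i]]] %||% character(0), chain_tokens)
    if (any(vapply(ann, function(b) is_contiguous_sub(toks[[i]], b), logical(1)))) {
      cand[i, reason := "rule3_annotated_or_truncation"]
      next
    }
    m <- parse_chain(cand$chain[i])
    sup <- sr[cand$chrom[i] == chrom & strand == cand$strand[i]][
      data.table(start = m[, "donor"], end = m[, "acceptor"]),
      on = c("start", "end")]$count
    sup[is.na(sup)] <- 0L
    n_int <- nrow(m)
    if (n_int >= 2L) {
      # internal exon j lies between introns j and j+1
      exon_ok <- sup[-n_int] >= min_support & sup[-1L] >= min_support
      if (!all(exon_ok)) {
        cand[i, reason := "rule4_internal_exon_support"]
        next
      }
    }
    if (any(sup < min_support)) {
      cand[i, reason := "rule5_intron_support"]
      next
    }
    cand[i, accepted := TRUE]
  }

  # rule 6: drop survivors that are contiguous proper subsequences of another
  # survivor on the same chromosome/strand
  surv <- which(cand$accepted)
  for (i in surv) {
    for (j in surv) {
      if (i == j) next
      if (cand$chrom[i] != cand$chrom[j] || cand$strand[i] != cand$strand[j]) next
      if (length(toks[[i]]) < length(toks[[j]]) &&
          is_contiguous_sub(toks[[i]], toks[[j]])) {
        cand[i, `:=`(accepted = FALSE, reason = "rule6_truncation_of_novel")]
        break
      }
    }
  }
  cand[, .(gene_id, chain, n_reads, rep_start, rep_end, accepted, reason,
           chrom, strand)]
}

# exon table for one novel chain given representative read ends
novel_exons <- function(gene_id, transcript_id, chrom, strand, chain,
                        rep_start, rep_end) {
  m <- parse_chain(chain)
  starts <- c(rep_start, m[, "acceptor"])
  ends <- c(m[, "donor"], rep_end)
  data.table(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
             strand = strand, start = starts, end = ends,
             exon_rank = seq_along(starts))
}

#' Write the enhanced annotation and per-group novel-isoform counts
#'
#' Appends accepted novel isoforms to the annotation as new transcripts
#' (source `isodie_novel`, transcript ids `NOVEL_<gene>_<i>`) and writes a
#' counts TSV with one row per isoform and one column per cell group.
#'
#' @param novel result of [discover_novel()] (only `accepted` rows are used).
#' @param genes a `gene_set`.
#' @param csmm CSMM table used for per-group counts.
#' @param group cell-group labels aligned with `csmm` (e.g.
#'   `"P7Hipp_OPCs"`-style sample_celltype labels); `NA` rows are ignored.
#' @param gtf_path,counts_path output paths.
#' @return invisible list with the novel exon table and the counts table.
#' @export
write_enhanced_annotation <- function(novel, genes, csmm, group,
                                      gtf_path, counts_path) {
  acc <- as.data.table(novel)[accepted == TRUE]
  if (nrow(acc)) {
    acc[, transcript_id := paste0("NOVEL_", gene_id, "_", seq_len(.N)), by = gene_id]
  } else {
    acc[, transcript_id := character(0)]
  }
  ex <- if (nrow(acc)) {
    rbindlist(lapply(seq_len(nrow(acc)), function(i) {
      novel_exons(acc$gene_id[i], acc$transcript_id[i], acc$chrom[i],
                  acc$strand[i], acc$chain[i], acc$rep_start[i], acc$rep_end[i])
    }))
  } else NULL
  export_annotation(genes, gtf_path, extra_exons = ex,
                    header = " enhanced annotation written by isodie")

  csmm <- as.data.table(csmm)
  keep <- !is.na(group)
  counts <- data.table(gene_id = csmm$gene_id[keep], chain = csmm$introns[keep],
                       group = as.character(group[keep]))
  counts <- counts[acc, on = c("gene_id", "chain"), nomatch = NULL][
    , .(count = .N), by = .(gene_id, transcript_id, group)]
  wide <- if (nrow(counts)) dcast(counts, gene_id + transcript_id ~ group,
                                  value.var = "count", fill = 0L)
  else data.table(gene_id = character(0), transcript_id = character(0))
  fwrite(wide, counts_path, sep = "\t")
  invisible(list(exons = ex, counts = wide))
}
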