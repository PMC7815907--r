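# Seeded synthetic-data generator: annotation, genome with planted splice
# motifs, CAGE/polyA peaks, barcode map and hierarchy, barcoded long reads
# drawn from per-cell-type isoform distributions, and a short-read junction
# support table -- together with a ground-truth ledger sufficient to
# recompute every expected pipeline output in the zero-noise limit.
#
# Gene model: each gene has a first exon, M internal exons and a last exon
# (exon length 150 bp, introns 300 bp). Annotated isoform 1 retains all
# internal exons; isoform j (j >= 2) skips internal exon j-1, so every
# annotated chain is distinct. Optional planted novel isoforms skip two
# adjacent internal exons (an unannotated junction), with decoy chains that
# must fail the intron-support and novel-truncation filters.

#' Validated simulation configuration
#'
#' Defaults describe the standard desk-scale study: 50 genes with 4 isoforms
#' each, two samples (brain regions) by four leaf cell types under a binary
#' hierarchy, 100 reads per gene per (sample, cell type), PacBio-scale
#' junction wobble, and a 5% 5'-truncation rate.
#'
#' @param n_genes number of genes.
#' @param n_isoforms annotated isoforms per gene (>= 2; >= 4 when novel
#'   isoforms are planted).
#' @param samples sample (region) labels.
#' @param cell_types leaf cell types.
#' @param hierarchy data.frame of `parent`, `child` edges; default binary tree
#'   `bulk -> {neurons, nonneurons} -> {EN, IN} / {Astro, Vasc}`.
#' @param depth reads per gene per (sample, cell type).
#' @param alpha Dirichlet concentration for per-gene isoform proportions
#'   (drawn once per gene, sorted so isoform 1 is the most abundant).
#' @param pi_list optional list of per-gene probability vectors overriding the
#'   Dirichlet draw (each must sum to 1).
#' @param n_die_genes genes with a planted differential-usage effect between
#'   the two samples.
#' @param die_dpi planted effect: probability mass moved away from isoform 1
#'   (spread over the remaining isoforms) in the second sample; the true
#'   delta-Pi, contributed by one isoform with an unambiguous direction.
#' @param die_cell_types `"all"` or a subset of `cell_types` carrying the
#'   effect (for attribution studies).
#' @param n_tss_variants 1 or 2; with 2, even-numbered isoforms start 400 bp
#'   further upstream with their own CAGE peak.
#' @param wobble_sd,wobble_max junction wobble: rounded Gaussian, clamped at
#'   `wobble_max` (must not exceed the platform tolerance for wobble to be
#'   recoverable by snapping).
#' @param truncation_rate fraction of spliced reads 5'-truncated past their
#'   first junction (they fail the completeness filter).
#' @param corrupt_rate fraction of spliced reads with one junction displaced
#'   by 5 bp on both sides (beyond snapping tolerance, so the splice motif
#'   lands on random sequence and the read fails the consensus filter with
#'   probability 253/256).
#' @param novel_genes genes carrying a planted novel isoform plus two decoy
#'   chains.
#' @param novel_frac,decoy_frac per-group read fraction of the novel chain
#'   and of each decoy chain in those genes.
#' @param novel_support short-read junction support planted for the novel
#'   junction (default 2 = the acceptance threshold); the unsupported decoy
#'   junction gets 1.
#' @param sr_support junction support planted for annotated introns.
#' @param peak_halfwidth CAGE/polyA peak half-width in bp.
#' @param end_jitter uniform read-end jitter in bp (within the peak window).
#' @param barcodes_per_type barcodes per leaf cell type.
#' @param platform `"PacBio"` (tolerance 2) or `"ONT"` (tolerance 3).
#' @param exact_counts deterministic largest-remainder isoform counts and all
#'   noise forced to zero (the zero-noise limit).
#' @param rrna_reads unspliced reads per sample planted on an rRNA gene (0 =
#'   no rRNA gene).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L, n_isoforms = 4L,
                       samples = c("HIPP", "PFC"),
                       cell_types = c("EN", "IN", "Astro", "Vasc"),
                       hierarchy = NULL,
                       depth = 100L, alpha = 4, pi_list = NULL,
                       n_die_genes = 10L, die_dpi = 0.3,
                       die_cell_types = "all",
                       n_tss_variants = 1L,
                       wobble_sd = 1, wobble_max = 2L,
                       truncation_rate = 0.05, corrupt_rate = 0,
                       novel_genes = 0L, novel_frac = 0.15, decoy_frac = 0.05,
                       novel_support = 2L, sr_support = 10L,
                       peak_halfwidth = 10L, end_jitter = 10L,
                       barcodes_per_type = 10L,
                       platform = c("PacBio", "ONT"),
                       exact_counts = FALSE, rrna_reads = 0L) {
  platform <- match.arg(platform)
  tol <- if (platform == "PacBio") 2L else 3L
  if (exact_counts) {
    wobble_sd <- 0; wobble_max <- 0L; truncation_rate <- 0
    corrupt_rate <- 0; end_jitter <- 0L
  }
  stopifnot(n_genes >= 1L, n_isoforms >= 2L, depth >= 1L,
            length(samples) == 2L, n_tss_variants %in% 1:2,
            die_dpi >= 0, die_dpi < 1, truncation_rate >= 0, corrupt_rate >= 0,
            truncation_rate + corrupt_rate <= 1)
  if (wobble_max > tol) stop("wobble_max exceeds the ", platform,
                             " tolerance (", tol, " bp); wobble would not be recoverable")
  if (novel_genes > 0L && n_isoforms < 4L) {
    stop("novel-isoform planting needs n_isoforms >= 4 (three internal exons)")
  }
  if (novel_genes > 0L && novel_frac + 2 * decoy_frac >= 0.9) {
    stop("novel_frac + 2*decoy_frac too large")
  }
  if (!is.null(pi_list)) {
    stopifnot(length(pi_list) == n_genes)
    for (p in pi_list) {
      if (length(p) != n_isoforms || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
        stop("each pi_list entry must be a length-", n_isoforms,
             " probability vector summing to 1")
      }
    }
  }
  if (is.null(hierarchy)) {
    hierarchy <- default_hierarchy(cell_types)
  }
  if (!identical(die_cell_types, "all")) {
    stopifnot(all(die_cell_types %in% cell_types))
  }
  structure(list(
    n_genes = as.integer(n_genes), n_isoforms = as.integer(n_isoforms),
    samples = samples, cell_types = cell_types, hierarchy = hierarchy,
    depth = as.integer(depth), alpha = alpha, pi_list = pi_list,
    n_die_genes = as.integer(min(n_die_genes, n_genes)), die_dpi = die_dpi,
    die_cell_types = die_cell_types, n_tss_variants = as.integer(n_tss_variants),
    wobble_sd = wobble_sd, wobble_max = as.integer(wobble_max),
    truncation_rate = truncation_rate, corrupt_rate = corrupt_rate,
    novel_genes = as.integer(novel_genes), novel_frac = novel_frac,
    decoy_frac = decoy_frac, novel_support = as.integer(novel_support),
    sr_support = as.integer(sr_support),
    peak_halfwidth = as.integer(peak_halfwidth),
    end_jitter = as.integer(end_jitter),
    barcodes_per_type = as.integer(barcodes_per_type),
    platform = platform, tolerance = tol,
    exact_counts = exact_counts, rrna_reads = as.integer(rrna_reads)),
    class = "sim_config")
}

default_hierarchy <- function(cell_types) {
  if (setequal(cell_types, c("EN", "IN", "Astro", "Vasc"))) {
    data.frame(parent = c("bulk", "bulk", "neurons", "neurons",
                          "nonneurons", "nonneurons"),
               child = c("neurons", "nonneurons", "EN", "IN", "Astro", "Vasc"))
  } else {
    data.frame(parent = "bulk", child = cell_types)
  }
}

# planted usage shift: isoform 1 loses `dpi`, compensated across the others.
# Spreading the gain keeps the true delta-Pi equal to `dpi` (one contributing
# isoform) with an unambiguous direction; a two-isoform swap would make the
# top-two positive and negative delta sums tie exactly.
shift_usage <- function(p, dpi) {
  k <- length(p)
  p + c(-dpi, rep(dpi / (k - 1), k - 1))
}

# largest-remainder integer allocation of `depth` among probabilities `p`
allocate_counts <- function(p, depth) {
  raw <- p * depth
  cnt <- floor(raw)
  rem <- depth - sum(cnt)
  if (rem > 0) {
    o <- order(raw - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  as.integer(cnt)
}

# exon-inclusion status of one isoform template against one exon, in the
# zero-noise limit (independent enumeration used by the truth ledger)
template_exon_status <- function(m, rstart, rend, es, ee, terminal) {
  donors <- m[, "donor"]; acceptors <- m[, "acceptor"]
  if (terminal) {
    overlap <- any(donors < ee & acceptors > es)
    if (rstart <= es && rend >= ee && !overlap) return("included")
    if (any(donors <= es & acceptors >= ee)) return("excluded")
    return("discarded")
  }
  if (any(acceptors == es) && any(donors == ee)) return("included")
  if (rstart <= es && rend >= ee) return("excluded")
  "discarded"
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Deterministic for a given `(config, seed)` pair: identical seeds give
#' byte-identical outputs through [write_sim_dataset()].
#'
#' @param config a [sim_config()].
#' @param seed integer seed for all randomness.
#' @return a `sim_data` list: `genes` (a `gene_set`), `genome`
#'   (`genome_seq`), `cage`, `polya` (`peak_set`s), `cellmap`
#'   (`cell_type_map`), `reads` (alignment table with a `sample` column),
#'   `sr_junctions`, `truth` (ledger: `isoforms`, `pi`, `reads`, `novel`,
#'   `exon_status`, `die_genes`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cf <- config
  L <- 150L; IL <- 300L; EXT <- 400L
  M <- cf$n_isoforms - 1L           # internal exons
  chrom <- "chrS1"

  gene_ids <- sprintf("G%04d", seq_len(cf$n_genes))
  die_genes <- if (cf$n_die_genes > 0L) gene_ids[seq_len(cf$n_die_genes)] else character(0)
  novel_gene_ids <- if (cf$novel_genes > 0L)
    gene_ids[seq(cf$n_genes - cf$novel_genes + 1L, cf$n_genes)] else character(0)

  gene_width <- 500L + (M + 2L) * (L + IL) + EXT + 500L
  offsets <- 1000L + (seq_len(cf$n_genes) - 1L) * (gene_width + 500L)

  exon_rows <- vector("list", cf$n_genes)
  peak_rows <- vector("list", cf$n_genes)
  iso_rows <- vector("list", cf$n_genes)
  motif_rows <- vector("list", cf$n_genes)
  novel_rows <- vector("list", cf$n_genes)
  sr_rows <- vector("list", cf$n_genes)

  for (g in seq_len(cf$n_genes)) {
    gid <- gene_ids[g]
    strand <- if (g %% 2L == 1L) "+" else "-"
    s0 <- offsets[g] + EXT + 100L
    ex_start <- s0 + (0:(M + 1L)) * (L + IL)
    ex_end <- ex_start + L
    n_ex <- M + 2L

    # isoform templates: retained exon indices (1-based over the skeleton)
    iso_exons <- c(list(seq_len(n_ex)),
                   lapply(seq_len(M), function(j) setdiff(seq_len(n_ex), j + 1L)))
    iso_ids <- sprintf("%s.t%d", gid, seq_len(cf$n_isoforms))

    # TSS/polyA variants: variant 2 extends the 5' terminal exon upstream
    variant_of <- if (cf$n_tss_variants == 2L) ((seq_len(cf$n_isoforms) - 1L) %% 2L) + 1L
                  else rep(1L, cf$n_isoforms)

    build_iso <- function(keep, variant) {
      st <- ex_start[keep]; en <- ex_end[keep]
      if (variant == 2L) {
        if (strand == "+") st[1L] <- st[1L] - EXT else en[length(en)] <- en[length(en)] + EXT
      }
      list(start = st, end = en,
           chain = chain_string(en[-length(en)], st[-1L]))
    }
    iso_tpl <- Map(build_iso, iso_exons, as.list(variant_of))

    exon_rows[[g]] <- rbindlist(lapply(seq_along(iso_tpl), function(j) {
      data.table(transcript_id = iso_ids[j], gene_id = gid, chrom = chrom,
                 strand = strand, start = iso_tpl[[j]]$start, end = iso_tpl[[j]]$end)
    }))

    # peaks at the biological 5'/3' ends of each variant
    tss_point <- function(variant) {
      if (strand == "+") (if (variant == 2L) s0 - EXT else s0)
      else (if (variant == 2L) ex_end[n_ex] + EXT else ex_end[n_ex]) - 1L
    }
    pa_point <- function() if (strand == "+") ex_end[n_ex] - 1L else s0
    hw <- cf$peak_halfwidth
    vs <- seq_len(cf$n_tss_variants)
    cage <- data.table(chrom = chrom, start = vapply(vs, tss_point, 0L) - hw,
                       end = vapply(vs, tss_point, 0L) + hw,
                       peak_id = sprintf("CAGE_%s_v%d", gid, vs),
                       strand = strand, kind = "CAGE")
    pa <- data.table(chrom = chrom, start = pa_point() - hw, end = pa_point() + hw,
                     peak_id = sprintf("PA_%s", gid), strand = strand, kind = "polyA")
    peak_rows[[g]] <- rbind(cage, pa)

    tss_peak_of <- sprintf("CAGE_%s_v%d", gid, variant_of)
    pa_peak_of <- rep(sprintf("PA_%s", gid), cf$n_isoforms)

    iso_tab <- data.table(
      gene_id = gid, iso = iso_ids, kind = "annotated",
      chain = vapply(iso_tpl, `[[`, "", "chain"),
      tpl_start = vapply(iso_tpl, function(t) min(t$start), 0L),
      tpl_end = vapply(iso_tpl, function(t) max(t$end), 0L),
      tss_peak_id = tss_peak_of, polya_peak_id = pa_peak_of,
      chrom = chrom, strand = strand)

    # planted novel + decoy chains
    if (gid %in% novel_gene_ids) {
      nv_keep <- c(1L, seq(4L, n_ex))                # skip internal exons 1-2
      nv <- build_iso(nv_keep, 1L)
      d6 <- list(start = c(ex_start[1L], ex_start[4L]),
                 end = c(ex_end[1L], ex_end[n_ex]),
                 chain = chain_string(ex_end[1L], ex_start[4L]))
      # d5: exonic through internal exon 1 (retaining the first intron), then
      # a single unannotated, unsupported junction straight to the last exon
      d5 <- list(start = c(ex_start[1L], ex_start[n_ex]),
                 end = c(ex_end[2L], ex_end[n_ex]),
                 chain = chain_string(ex_end[2L], ex_start[n_ex]))
      iso_tab <- rbind(iso_tab, data.table(
        gene_id = gid,
        iso = paste0(gid, c(".novel", ".decoy6", ".decoy5")),
        kind = c("novel", "decoy_rule6", "decoy_rule5"),
        chain = c(nv$chain, d6$chain, d5$chain),
        tpl_start = c(min(nv$start), min(d6$start), min(d5$start)),
        tpl_end = c(max(nv$end), max(d6$end), max(d5$end)),
        tss_peak_id = sprintf("CAGE_%s_v1", gid), polya_peak_id = sprintf("PA_%s", gid),
        chrom = chrom, strand = strand))
      novel_rows[[g]] <- data.table(
        gene_id = gid,
        chain = c(nv$chain, d6$chain, d5$chain),
        expected_accept = c(TRUE, FALSE, FALSE),
        expected_rule = c("", "rule6_truncation_of_novel", "rule5_intron_support"))
    }

    # short-read junction support: annotated introns + planted novel junctions
    all_introns <- unique(rbindlist(lapply(iso_tab$chain, function(ch) {
      m <- parse_chain(ch)
      if (nrow(m) == 0L) return(NULL)
      data.table(start = m[, "donor"], end = m[, "acceptor"])
    })))
    ann_introns <- unique(rbindlist(lapply(
      iso_tab[kind == "annotated", chain], function(ch) {
        m <- parse_chain(ch)
        data.table(start = m[, "donor"], end = m[, "acceptor"])
      })))
    all_introns[, count := cf$sr_support]
    if (gid %in% novel_gene_ids) {
      nv_introns <- parse_chain(iso_tab[kind == "novel", chain])
      d5_introns <- parse_chain(iso_tab[kind == "decoy_rule5", chain])
      is_ann <- function(s, e) any(ann_introns$start == s & ann_introns$end == e)
      for (r in seq_len(nrow(nv_introns))) {
        if (!is_ann(nv_introns[r, "donor"], nv_introns[r, "acceptor"])) {
          all_introns[start == nv_introns[r, "donor"] & end == nv_introns[r, "acceptor"],
                      count := cf$novel_support]
        }
      }
      for (r in seq_len(nrow(d5_introns))) {
        if (!is_ann(d5_introns[r, "donor"], d5_introns[r, "acceptor"])) {
          all_introns[start == d5_introns[r, "donor"] & end == d5_introns[r, "acceptor"],
                      count := 1L]
        }
      }
    }
    sr_rows[[g]] <- data.table(chrom = chrom, all_introns[, .(start, end)],
                               strand = strand, count = all_introns$count)

    # splice-motif positions (strand-aware), planted for every junction used
    motif_rows[[g]] <- data.table(donor = all_introns$start, acceptor = all_introns$end,
                                  strand = strand)
    iso_rows[[g]] <- iso_tab
  }

  exons <- rbindlist(exon_rows)
  isoforms <- rbindlist(iso_rows)
  peaks <- rbindlist(peak_rows)
  sr_junctions <- rbindlist(sr_rows)
  truth_novel <- rbindlist(novel_rows[!vapply(novel_rows, is.null, TRUE)])
  if (is.null(truth_novel) || nrow(truth_novel) == 0L) {
    truth_novel <- data.table(gene_id = character(0), chain = character(0),
                              expected_accept = logical(0), expected_rule = character(0))
  }

  gene_meta <- NULL
  if (cf$rrna_reads > 0L) {
    # an rRNA gene parked after the last protein-coding gene
    rs <- offsets[cf$n_genes] + gene_width + 2000L
    exons <- rbind(exons, data.table(transcript_id = "RRNA1.t1", gene_id = "RRNA1",
                                     chrom = chrom, strand = "+",
                                     start = rs, end = rs + 150L))
    gene_meta <- data.table(gene_id = "RRNA1", gene_name = "Rn45s", rrna = TRUE)
  }
  gs <- gene_set(exons, gene_meta = gene_meta)

  # genome with planted motifs
  glen <- max(exons$end) + 2000L
  base <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  motifs <- rbindlist(motif_rows)
  plus <- motifs$strand == "+"
  # + strand: GT..AG ; - strand: CT..AC (so the reverse complement reads GT..AG)
  d <- motifs$donor; a <- motifs$acceptor
  base[d[plus] + 1L] <- "G"; base[d[plus] + 2L] <- "T"
  base[a[plus] - 1L] <- "A"; base[a[plus]] <- "G"
  base[d[!plus] + 1L] <- "C"; base[d[!plus] + 2L] <- "T"
  base[a[!plus] - 1L] <- "A"; base[a[!plus]] <- "C"
  genome <- structure(setNames(paste(base, collapse = ""), chrom), class = "genome_seq")

  cage_ps <- peaks[kind == "CAGE", .(chrom, start, end, peak_id, strand)]
  pa_ps <- peaks[kind == "polyA", .(chrom, start, end, peak_id, strand)]
  setorder(cage_ps, chrom, start, end); setorder(pa_ps, chrom, start, end)
  cage_ps <- structure(cage_ps, class = c("peak_set", class(cage_ps)), kind = "CAGE")
  pa_ps <- structure(pa_ps, class = c("peak_set", class(pa_ps)), kind = "polyA")

  # barcodes: unique random 12-mers per leaf cell type
  n_bc <- cf$barcodes_per_type * length(cf$cell_types)
  repeat {
    bcs <- vapply(seq_len(n_bc), function(i)
      paste(sample(c("A", "C", "G", "T"), 12L, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(bcs)) break
  }
  bc_map <- data.table(barcode = bcs,
                       cell_type = rep(cf$cell_types, each = cf$barcodes_per_type))
  cellmap <- cell_type_map(bc_map, cf$hierarchy)
  bc_pool <- split(bc_map$barcode, bc_map$cell_type)

  # per-gene isoform probabilities
  die_types <- if (identical(cf$die_cell_types, "all")) cf$cell_types else cf$die_cell_types
  pi_base <- vector("list", cf$n_genes)
  for (g in seq_len(cf$n_genes)) {
    if (!is.null(cf$pi_list)) {
      pi_base[[g]] <- cf$pi_list[[g]]
    } else {
      for (try in 1:200) {
        p <- sort(rgamma(cf$n_isoforms, cf$alpha), decreasing = TRUE)
        p <- p / sum(p)
        if (!(gene_ids[g] %in% die_genes) || p[1L] >= cf$die_dpi + 0.05) break
      }
      pi_base[[g]] <- p
    }
  }

  # assemble reads: one block per (gene, sample, cell_type)
  setkey(isoforms, gene_id)
  read_blocks <- list(); truth_pi_blocks <- list()
  blk <- 0L
  for (g in seq_len(cf$n_genes)) {
    gid <- gene_ids[g]
    iso_g <- isoforms[.(gid)]
    ann <- which(iso_g$kind == "annotated")
    n_all <- nrow(iso_g)
    for (s_i in seq_along(cf$samples)) {
      smp <- cf$samples[s_i]
      for (ct in cf$cell_types) {
        p_ann <- pi_base[[g]]
        if (gid %in% die_genes && s_i == 2L && ct %in% die_types) {
          p_ann <- shift_usage(p_ann, cf$die_dpi)
        }
        p_all <- numeric(n_all)
        p_all[ann] <- p_ann
        if (n_all > length(ann)) {
          extra <- c(cf$novel_frac, cf$decoy_frac, cf$decoy_frac)
          p_all[-ann] <- extra
          p_all[ann] <- p_ann * (1 - sum(extra))
        }
        cnt <- if (cf$exact_counts) allocate_counts(p_all, cf$depth)
               else as.integer(rmultinom(1L, cf$depth, p_all))
        blk <- blk + 1L
        read_blocks[[blk]] <- data.table(
          gene_row = g, iso_row = rep(seq_len(n_all), cnt),
          sample = smp, cell_type = ct)
        truth_pi_blocks[[blk]] <- data.table(
          gene_id = gid, iso = iso_g$iso, kind = iso_g$kind, sample = smp,
          cell_type = ct, pi_true = p_all, count = cnt)
      }
    }
  }
  rd <- rbindlist(read_blocks)
  truth_pi <- rbindlist(truth_pi_blocks)

  setkey(isoforms, NULL)
  iso_idx <- cumsum_offsets(isoforms$gene_id, gene_ids)[rd$gene_row] + rd$iso_row
  n_reads <- nrow(rd)
  bc <- character(n_reads)
  for (ct in cf$cell_types) {
    sel <- which(rd$cell_type == ct)
    bc[sel] <- sample(bc_pool[[ct]], length(sel), replace = TRUE)
  }
  reads <- data.table(
    read_id = sprintf("r%07d", seq_len(n_reads)),
    barcode = bc,
    chrom = chrom,
    strand = isoforms$strand[iso_idx],
    start = isoforms$tpl_start[iso_idx],
    end = isoforms$tpl_end[iso_idx],
    introns = isoforms$chain[iso_idx],
    mapq = 60L,
    sample = rd$sample)

  truth_reads <- data.table(read_id = reads$read_id, gene_id = gene_ids[rd$gene_row],
                            iso = isoforms$iso[iso_idx], kind = isoforms$kind[iso_idx],
                            sample = rd$sample, cell_type = rd$cell_type,
                            corrupted = FALSE, truncated = FALSE)

  # end jitter (within the peak matching window)
  if (cf$end_jitter > 0L) {
    reads[, start := start + sample(seq(-cf$end_jitter, cf$end_jitter), .N, TRUE)]
    reads[, end := end + sample(seq(-cf$end_jitter, cf$end_jitter), .N, TRUE)]
  }

  # junction noise: corruption (both boundaries of the first junction moved
  # 5 bp inward) takes precedence over wobble on that junction
  long <- chains_to_long(reads$introns)
  spliced <- unique(long$read_idx)
  if (cf$corrupt_rate > 0 && length(spliced)) {
    corr <- spliced[runif(length(spliced)) < cf$corrupt_rate]
    long[, corrupted := read_idx %in% corr & pos == 1L]
    long[corrupted == TRUE, `:=`(donor = donor + 5L, acceptor = acceptor - 5L)]
    truth_reads[corr, corrupted := TRUE]
  } else long[, corrupted := FALSE]
  if (cf$wobble_max > 0L && nrow(long)) {
    wob <- function(n) pmin(pmax(as.integer(round(rnorm(n, 0, cf$wobble_sd))),
                                 -cf$wobble_max), cf$wobble_max)
    long[corrupted == FALSE, `:=`(donor = donor + wob(.N), acceptor = acceptor + wob(.N))]
  }
  # truncation: biological 5' end moved past the first junction
  if (cf$truncation_rate > 0 && length(spliced)) {
    trunc <- spliced[runif(length(spliced)) < cf$truncation_rate]
    trunc <- setdiff(trunc, which(truth_reads$corrupted))
    if (length(trunc)) {
      tr_strand <- reads$strand[trunc]
      first_j <- long[pos == 1L][read_idx %in% trunc]
      setkey(first_j, read_idx)
      last_j <- long[read_idx %in% trunc, .SD[which.max(pos)], by = read_idx]
      setkey(last_j, read_idx)
      plus_r <- trunc[tr_strand == "+"]; minus_r <- trunc[tr_strand == "-"]
      if (length(plus_r)) {
        reads[plus_r, start := first_j[.(plus_r), acceptor] + 10L]
        long <- long[!(read_idx %in% plus_r & pos == 1L)]
      }
      if (length(minus_r)) {
        mx <- last_j[.(minus_r)]
        reads[minus_r, end := mx$donor - 10L]
        long <- long[!mx, on = c("read_idx", "pos")]
      }
      truth_reads[trunc, truncated := TRUE]
    }
  }
  reads[, introns := long_to_chains(long[, .(read_idx, donor, acceptor)], nrow(reads))]

  # rRNA-overlapping unspliced reads
  if (cf$rrna_reads > 0L) {
    rr <- gs$genes[gene_id == "RRNA1"]
    rr_reads <- data.table(
      read_id = sprintf("rrna%05d", seq_len(cf$rrna_reads * length(cf$samples))),
      barcode = NA_character_, chrom = chrom, strand = "+",
      start = rr$start + 10L, end = rr$end - 10L, introns = "", mapq = 60L,
      sample = rep(cf$samples, each = cf$rrna_reads))
    reads <- rbind(reads, rr_reads)
  }

  # zero-noise exon-status truth per (isoform template, exon)
  cat <- exon_catalog(gs)
  status_rows <- vector("list", nrow(isoforms))
  for (i in seq_len(nrow(isoforms))) {
    ce <- cat[gene_id == isoforms$gene_id[i]]
    if (nrow(ce) == 0L) next
    m <- parse_chain(isoforms$chain[i])
    st <- vapply(seq_len(nrow(ce)), function(j)
      template_exon_status(m, isoforms$tpl_start[i], isoforms$tpl_end[i],
                           ce$start[j], ce$end[j], ce$terminal[j]),
      character(1))
    status_rows[[i]] <- data.table(gene_id = isoforms$gene_id[i], iso = isoforms$iso[i],
                                   exon_id = ce$exon_id, status = st)
  }
  truth_exon <- rbindlist(status_rows)

  truth <- list(isoforms = isoforms[, .(gene_id, iso, kind, chain, tss_peak_id,
                                        polya_peak_id, tpl_start, tpl_end,
                                        chrom, strand)],
                pi = truth_pi, reads = truth_reads, novel = truth_novel,
                exon_status = truth_exon,
                die_genes = data.table(gene_id = gene_ids,
                                       true_dpi = ifelse(gene_ids %in% die_genes,
                                                         cf$die_dpi, 0),
                                       die_cell_types = paste(die_types, collapse = ",")))
  structure(list(genes = gs, genome = genome, cage = cage_ps, polya = pa_ps,
                 cellmap = cellmap, reads = reads[], sr_junctions = sr_junctions,
                 truth = truth, config = cf),
            class = "sim_data")
}

# row offset of each gene's first isoform in the isoform table
cumsum_offsets <- function(iso_gene_ids, gene_ids) {
  n_per <- table(factor(iso_gene_ids, levels = gene_ids))
  c(0L, cumsum(as.integer(n_per)))[seq_along(gene_ids)]
}

#' Simulate under the null (identical isoform usage everywhere)
#'
#' @inheritParams simulate_dataset
#' @return a `sim_data` with `true_dpi = 0` for every gene.
#' @export
simulate_null <- function(config = sim_config(), seed = 1L) {
  cfg <- unclass(config)
  cfg$n_die_genes <- 0L
  config <- do.call(sim_config, cfg[setdiff(names(cfg), c("tolerance"))])
  simulate_dataset(config, seed)
}

#' @export
print.sim_data <- function(x, ...) {
  cat("<sim_data> ", nrow(x$genes$genes), " genes, ", nrow(x$reads), " reads, ",
      length(x$config$samples), " samples x ", length(x$config$cell_types),
      " cell types (seeded)\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits GTF, genome FASTA, CAGE and polyA BED6, barcode and hierarchy TSVs,
#' the alignment table TSV, and the short-read junction support TSV.
#'
#' @param sim a `sim_data`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             fasta = file.path(dir, "genome.fa"),
             cage = file.path(dir, "cage.bed"),
             polya = file.path(dir, "polya.bed"),
             barcodes = file.path(dir, "barcodes.tsv"),
             hierarchy = file.path(dir, "hierarchy.tsv"),
             reads = file.path(dir, "reads.tsv"),
             junctions = file.path(dir, "junctions.tsv"))
  export_annotation(sim$genes, paths["gtf"])
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(sim$genome)), paths["fasta"])
  write_bed6 <- function(pk, path) {
    bed <- data.table(pk$chrom, pk$start, pk$end, pk$peak_id, 0L, pk$strand)
    fwrite(bed, path, sep = "\t", col.names = FALSE)
  }
  write_bed6(sim$cage, paths["cage"])
  write_bed6(sim$polya, paths["polya"])
  fwrite(data.table(barcode = names(sim$cellmap$map),
                    cell_type = unname(sim$cellmap$map)),
         paths["barcodes"], sep = "\t")
  fwrite(sim$cellmap$edges, paths["hierarchy"], sep = "\t")
  fwrite(sim$reads, paths["reads"], sep = "\t")
  fwrite(sim$sr_junctions, paths["junctions"], sep = "\t")
  invisible(paths)
}

#' Counts-level usage simulator for statistical property studies
#'
#' Draws per-gene isoform counts directly (multinomial at given depths) for
#' two groups, with an optional planted single-swap effect, bypassing read
#' generation. Used to study type-I error and power of [die_test_usage()] at
#' scale.
#'
#' @param n_genes number of genes.
#' @param n_isoforms isoforms per gene.
#' @param depth length-2 read depths for groups A and B.
#' @param dpi planted effect: mass moved away from isoform 1 in group B,
#'   spread over the others (0 = null).
#' @param alpha Dirichlet concentration for the base proportions.
#' @param groups the two group labels.
#' @return list: `ut` (a `usage_tables`), `truth` (per-gene base proportions
#'   and true delta-Pi).
#' @export
simulate_usage <- function(n_genes = 1000L, n_isoforms = 4L,
                           depth = c(100L, 100L), dpi = 0,
                           alpha = 4, groups = c("A", "B")) {
  stopifnot(length(depth) == 2L, dpi >= 0, dpi < 1)
  rows <- vector("list", n_genes)
  truth <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    repeat {
      p <- sort(rgamma(n_isoforms, alpha), decreasing = TRUE)
      p <- p / sum(p)
      if (dpi == 0 || p[1L] >= dpi + 0.05) break
    }
    pb <- shift_usage(p, dpi)
    ca <- as.integer(rmultinom(1L, depth[1L], p))
    cb <- as.integer(rmultinom(1L, depth[2L], pb))
    gid <- sprintf("G%05d", g)
    keys <- sprintf("%s|iso%02d", gid, seq_len(n_isoforms))
    rows[[g]] <- data.table(gene_id = gid,
                            group = rep(groups, each = n_isoforms),
                            count = c(ca, cb))[, key := rep(keys, 2L)]
    truth[[g]] <- data.table(gene_id = gid, true_dpi = dpi)
  }
  ut <- rbindlist(rows)[count > 0L]
  setattr(ut, "feature", "isoform")
  setattr(ut, "class", c("usage_tables", class(ut)))
  list(ut = ut[], truth = rbindlist(truth))
}
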