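# Reference input readers. Everything downstream uses one coordinate
# convention: 0-based half-open intervals. GTF input (1-based inclusive) is
# shifted on load and shifted back on export; BED input is already 0-based
# half-open. Introns are stored as (first intronic base, one-past-last
# intronic base), so a donor coordinate equals the end of the upstream exon
# and an acceptor coordinate equals the start of the downstream exon.

#' Load a gene annotation from GTF
#'
#' Parses a GENCODE/Ensembl-dialect GTF into a `gene_set`: gene and transcript
#' tables, exon and intron tables, per-transcript intron-chain strings, a
#' splice-site index mapping `(chrom, coordinate, strand)` to gene ids, and an
#' rRNA flag per gene used by the read filter.
#'
#' rRNA genes are flagged when any of their `gene_biotype` /
#' `transcript_biotype` attributes equal `"rRNA"` or when the gene name or id
#' matches `rrna_pattern` (how the original analyses identified rRNA genes is
#' not specified, so the pattern is configurable).
#'
#' @param gtf_path path to a GTF file with exon features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @param rrna_pattern regular expression applied to gene name and id
#'   (case-insensitive by construction of the default).
#' @return an object of class `gene_set`.
#' @export
load_annotation <- function(gtf_path, rrna_pattern = "rRNA|^(mt-)?Rn[0-9]") {
  lines <- readLines(gtf_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    bad <- which(body)[which(nf < 9L)[1]]
    stop("malformed GTF line ", bad, " in ", gtf_path, ": expected 9 tab-separated fields")
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  feat <- as.character(md$type)
  ex <- gr[feat == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon features: ", gtf_path)
  exd <- data.table(
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(ex))
  if (anyNA(exd$transcript_id) || anyNA(exd$gene_id)) {
    stop("exon feature without gene_id/transcript_id attribute in ", gtf_path)
  }

  # biotype / name lookup per gene for rRNA flagging
  gname <- rep(NA_character_, length(gr))
  for (col in c("gene_name", "gene")) {
    if (col %in% names(md)) gname <- ifelse(is.na(gname), as.character(md[[col]]), gname)
  }
  biot <- rep(NA_character_, length(gr))
  for (col in c("gene_biotype", "gene_type", "transcript_biotype", "transcript_type")) {
    if (col %in% names(md)) biot <- ifelse(is.na(biot), as.character(md[[col]]), biot)
  }
  gid_all <- as.character(md$gene_id)
  meta <- data.table(gene_id = gid_all, gname = gname, biot = biot)[!is.na(gene_id)]
  meta <- meta[, .(gene_name = {v <- gname[!is.na(gname)]; if (length(v)) v[1] else NA_character_},
                   rrna = any(biot == "rRNA", na.rm = TRUE)), by = gene_id]
  meta[, rrna := rrna |
         grepl(rrna_pattern, gene_id, ignore.case = TRUE) |
         (!is.na(gene_name) & grepl(rrna_pattern, gene_name, ignore.case = TRUE))]

  gene_set(exd, gene_meta = meta)
}

#' Construct a gene_set from an exon table
#'
#' The shared constructor behind [load_annotation()] (and the synthetic-data
#' generator): derives transcripts, introns, intron-chain strings and the
#' splice-site index from per-transcript exon intervals in the internal
#' 0-based half-open convention.
#'
#' @param exons data.frame with columns `transcript_id, gene_id, chrom,
#'   strand, start, end` (one row per exon).
#' @param gene_meta optional data.frame with `gene_id` and any of `gene_name`,
#'   `rrna`.
#' @return a `gene_set`.
#' @export
gene_set <- function(exons, gene_meta = NULL) {
  exd <- as.data.table(exons)[, .(transcript_id = as.character(transcript_id),
                                  gene_id = as.character(gene_id),
                                  chrom = as.character(chrom),
                                  strand = as.character(strand),
                                  start = as.integer(start),
                                  end = as.integer(end))]
  setorder(exd, transcript_id, start)
  exd[, exon_rank := seq_len(.N), by = transcript_id]
  if (exd[, .(bad = .N > 1L && any(start[-1L] < end[-.N])), by = transcript_id][, any(bad)]) {
    stop("overlapping exons within one transcript")
  }

  tx <- exd[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
                start = min(start), end = max(end), n_exons = .N),
            by = transcript_id]

  introns <- exd[, if (.N > 1L) .(gene_id = gene_id[1L], chrom = chrom[1L],
                                  strand = strand[1L],
                                  start = end[-.N], end = start[-1L]),
                 by = transcript_id]
  if (nrow(introns) == 0L) {
    introns <- data.table(transcript_id = character(0), gene_id = character(0),
                          chrom = character(0), strand = character(0),
                          start = integer(0), end = integer(0))
  }

  chains <- setNames(rep("", nrow(tx)), tx$transcript_id)
  if (nrow(introns)) {
    cc <- introns[order(start), .(chain = paste(paste0(start, "-", end), collapse = ";")),
                  by = transcript_id]
    chains[cc$transcript_id] <- cc$chain
  }

  genes <- tx[, .(chrom = chrom[1L], strand = strand[1L],
                  start = min(start), end = max(end)), by = gene_id]
  if (!is.null(gene_meta)) {
    gene_meta <- as.data.table(gene_meta)
    genes <- merge(genes, gene_meta, by = "gene_id", all.x = TRUE)
  }
  if (!"gene_name" %in% names(genes)) genes[, gene_name := NA_character_]
  if (!"rrna" %in% names(genes)) genes[, rrna := FALSE]
  genes[is.na(rrna), rrna := FALSE]
  setorder(genes, chrom, start)

  sites <- rbind(
    introns[, .(chrom, coord = start, strand, gene_id, site = "donor")],
    introns[, .(chrom, coord = end, strand, gene_id, site = "acceptor")])
  sites <- unique(sites)
  setkey(sites, chrom, strand, coord)

  structure(list(genes = genes, transcripts = tx, exons = exd,
                 introns = introns, chains = chains, splice_sites = sites),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", nrow(x$genes), " genes, ", nrow(x$transcripts),
      " transcripts, ", nrow(x$exons), " exons, ",
      nrow(unique(x$splice_sites[, .(chrom, strand, coord)])),
      " distinct splice sites, ", sum(x$genes$rrna), " rRNA genes\n", sep = "")
  invisible(x)
}

# Internal GTF writer (formatting only; parsing stays with rtracklayer).
# tx_tab: transcript_id, gene_id, chrom, strand, source; exon_tab: transcript_id,
# gene_id, chrom, strand, start, end (internal 0-based half-open).
format_gtf_lines <- function(exon_tab, source = "isodie") {
  exon_tab <- as.data.table(exon_tab)
  setorder(exon_tab, chrom, transcript_id, start)
  tx <- exon_tab[, .(gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
                     start = min(start), end = max(end)), by = transcript_id]
  gn <- tx[, .(chrom = chrom[1L], strand = strand[1L],
               start = min(start), end = max(end)), by = gene_id]
  attr_g <- function(g) sprintf('gene_id "%s";', g)
  attr_t <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  lines <- c(
    sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
            gn$chrom, source, gn$start + 1L, gn$end, gn$strand, attr_g(gn$gene_id)),
    sprintf("%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom, source, tx$start + 1L, tx$end, tx$strand,
            attr_t(tx$gene_id, tx$transcript_id)),
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
            exon_tab$chrom, source, exon_tab$start + 1L, exon_tab$end,
            exon_tab$strand, attr_t(exon_tab$gene_id, exon_tab$transcript_id)))
  lines
}

#' Write a gene_set back to GTF
#'
#' Inverse of [load_annotation()] on exon coordinates (round-trip identity).
#'
#' @param gs a `gene_set`.
#' @param path output GTF path.
#' @param extra_exons optional extra exon table (same columns as `gs$exons`)
#'   appended as additional transcripts, written with source `isodie_novel`.
#' @param header optional comment line(s) written at the top.
#' @return `path`, invisibly.
#' @export
export_annotation <- function(gs, path, extra_exons = NULL, header = NULL) {
  lines <- format_gtf_lines(gs$exons)
  if (!is.null(extra_exons) && nrow(extra_exons)) {
    lines <- c(lines, format_gtf_lines(extra_exons, source = "isodie_novel"))
  }
  writeLines(c(if (!is.null(header)) paste0("#", header), lines), path)
  invisible(path)
}

#' Load CAGE or polyA peaks from BED6
#'
#' @param bed_path path to a BED6 file (0-based half-open, strand column).
#' @param kind `"CAGE"` or `"polyA"`.
#' @return an object of class `peak_set`: a data.table with columns
#'   `chrom, start, end, peak_id, strand`, sorted by position. Peaks named
#'   `"."` (or unnamed) get stable ids `chrom:start-end:strand`, deduplicated
#'   with a numeric suffix when identical intervals repeat.
#' @export
load_peaks <- function(bed_path, kind = c("CAGE", "polyA")) {
  kind <- match.arg(kind)
  if (file.size(bed_path) == 0L) {
    pk <- data.table(chrom = character(0), start = integer(0), end = integer(0),
                     peak_id = character(0), strand = character(0))
    return(structure(pk, class = c("peak_set", class(pk)), kind = kind))
  }
  gr <- rtracklayer::import(bed_path, format = "BED")
  pk <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    peak_id = if (!is.null(gr$name)) as.character(gr$name) else NA_character_,
    strand = as.character(GenomicRanges::strand(gr)))
  auto <- is.na(pk$peak_id) | pk$peak_id == "." | pk$peak_id == ""
  pk[auto == TRUE, peak_id := sprintf("%s:%d-%d:%s", chrom, start, end, strand)]
  if (anyDuplicated(pk$peak_id)) {
    pk[, peak_id := if (.N > 1L) paste0(peak_id, "#", seq_len(.N)) else peak_id,
       by = peak_id]
  }
  setorder(pk, chrom, start, end)
  structure(pk, class = c("peak_set", class(pk)), kind = kind)
}

#' Load a barcode-to-cell-type map and a cell-group hierarchy
#'
#' @param map_path TSV with columns `barcode`, `cell_type` (header optional).
#' @param hierarchy_path either a TSV edge list with columns `parent`, `child`
#'   (header optional) or a JSON file of nested objects
#'   (`{"bulk": {"neurons": {...}}}`).
#' @return an object of class `cell_type_map` with elements `map` (named
#'   character vector barcode -> leaf cell type), `edges`, `root`, `leaves`.
#'   Duplicate barcodes with identical labels are deduplicated with a warning;
#'   conflicting labels, cycles, multiple roots, or barcodes mapped to
#'   non-leaf groups are errors.
#' @export
load_cell_map <- function(map_path, hierarchy_path) {
  mp <- read_tsv_flex(map_path, c("barcode", "cell_type"))
  edges <- if (grepl("\\.json$", hierarchy_path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("JSON hierarchy requires the jsonlite package")
    }
    tree <- jsonlite::fromJSON(hierarchy_path, simplifyVector = FALSE)
    as.data.table(json_tree_edges(tree))
  } else {
    read_tsv_flex(hierarchy_path, c("parent", "child"))
  }
  cell_type_map(mp, edges)
}

#' Construct a cell_type_map from in-memory tables
#'
#' @param map data.frame with columns `barcode`, `cell_type`.
#' @param edges data.frame with columns `parent`, `child`.
#' @return a `cell_type_map` (see [load_cell_map()]).
#' @export
cell_type_map <- function(map, edges) {
  map <- as.data.table(map)[, .(barcode = as.character(barcode),
                                cell_type = as.character(cell_type))]
  edges <- as.data.table(edges)[, .(parent = as.character(parent),
                                    child = as.character(child))]
  nodes <- union(edges$parent, edges$child)
  roots <- setdiff(edges$parent, edges$child)
  if (length(roots) != 1L) stop("hierarchy must have exactly one root, found: ",
                                paste(roots, collapse = ", "))
  # cycle check: iterative leaf-stripping (Kahn)
  remaining <- copy(edges)
  alive <- nodes
  repeat {
    leaf_now <- setdiff(alive, remaining$parent)
    drop <- remaining$child %in% leaf_now
    if (!any(drop)) break
    remaining <- remaining[!drop]
    alive <- setdiff(alive, setdiff(leaf_now, c(remaining$parent, remaining$child)))
    if (nrow(remaining) == 0L) break
  }
  if (nrow(remaining) > 0L) stop("cycle detected in cell-type hierarchy")
  leaves <- setdiff(nodes, edges$parent)

  dup <- duplicated(map)
  if (any(dup)) {
    warning(sum(dup), " duplicate barcode row(s) deduplicated")
    map <- unique(map)
  }
  if (anyDuplicated(map$barcode)) {
    bad <- map$barcode[duplicated(map$barcode)][1]
    stop("barcode mapped to conflicting cell types: ", bad)
  }
  unknown <- setdiff(unique(map$cell_type), nodes)
  if (length(unknown)) stop("cell types absent from hierarchy: ",
                            paste(unknown, collapse = ", "))
  nonleaf <- setdiff(unique(map$cell_type), leaves)
  if (length(nonleaf)) stop("barcodes mapped to non-leaf groups: ",
                            paste(nonleaf, collapse = ", "))
  structure(list(map = setNames(map$cell_type, map$barcode),
                 edges = edges, root = roots, leaves = leaves),
            class = "cell_type_map")
}

#' Leaves of the hierarchy under a node
#'
#' @param ctm a `cell_type_map`.
#' @param node a node name (default: the root).
#' @return character vector of leaf cell types under (and including) `node`.
#' @export
hierarchy_leaves <- function(ctm, node = ctm$root) {
  stopifnot(inherits(ctm, "cell_type_map"))
  if (!(node %in% c(ctm$edges$parent, ctm$edges$child))) {
    stop("unknown hierarchy node: ", node)
  }
  if (node %in% ctm$leaves) return(node)
  kids <- ctm$edges[parent == node, child]
  unlist(lapply(kids, hierarchy_leaves, ctm = ctm), use.names = FALSE)
}

#' Direct children of a hierarchy node
#' @param ctm a `cell_type_map`.
#' @param node a node name.
#' @return character vector of child node names.
#' @export
hierarchy_children <- function(ctm, node) {
  stopifnot(inherits(ctm, "cell_type_map"))
  ctm$edges[parent == node, child]
}

#' @export
print.cell_type_map <- function(x, ...) {
  cat("<cell_type_map> ", length(x$map), " barcodes, root '", x$root,
      "', leaves: ", paste(x$leaves, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# tolerate an optional header row matching the expected column names
read_tsv_flex <- function(path, cols) {
  dt <- as.data.table(read.table(path, sep = "\t", header = FALSE,
                                 colClasses = "character", quote = "",
                                 comment.char = "#"))
  if (ncol(dt) < length(cols)) stop("expected >= ", length(cols), " columns in ", path)
  dt <- dt[, seq_along(cols), with = FALSE]
  setnames(dt, cols)
  if (nrow(dt) && all(tolower(unlist(dt[1])) == tolower(cols))) dt <- dt[-1]
  dt
}

json_tree_edges <- function(tree, parent = NULL) {
  out <- list()
  for (nm in names(tree)) {
    if (!is.null(parent)) out[[length(out) + 1L]] <- data.frame(parent = parent, child = nm)
    kid <- tree[[nm]]
    if (is.list(kid) && length(kid)) out[[length(out) + 1L]] <- json_tree_edges(kid, nm)
  }
  do.call(rbind, out)
}

#' Load a genome FASTA as an in-memory sequence store
#'
#' @param fasta_path path to an (uncompressed or gzipped) FASTA file.
#' @return named character vector of chromosome sequences, class `genome_seq`.
#' @export
load_genome <- function(fasta_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  structure(seqs, class = "genome_seq")
}

#' Load a short-read splice-junction support table
#'
#' TSV with columns `chrom, start, end, strand, count`, coordinates in the
#' internal convention (intron first base, one-past-last base), `count` the
#' number of uniquely mapping spliced short reads supporting the junction.
#'
#' @param path TSV path.
#' @return data.table with those columns.
#' @export
load_junction_support <- function(path) {
  dt <- read_tsv_flex(path, c("chrom", "start", "end", "strand", "count"))
  dt[, `:=`(start = as.integer(start), end = as.integer(end), count = as.integer(count))]
  dt[]
}
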