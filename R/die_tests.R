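# Statistical core: gene-level isoform / TSS / polyA usage tests with
# delta-Pi effect sizes, exon-level 2x2 tests with delta-Psi, and BH/BY
# step-up multiple-testing corrections with per-test correction factors.

#' Pearson chi-square test on an n x 2 count table
#'
#' Plain Pearson statistic with `(n - 1)` degrees of freedom after dropping
#' all-zero rows; no continuity correction.
#'
#' @param counts integer matrix with two columns.
#' @return list with `statistic`, `df`, `p`, `n_rows` (rows tested); `p` is
#'   `NA` with `reason` set when a column sum is zero or fewer than two
#'   informative rows remain.
#' @export
chi2_nx2 <- function(counts) {
  stopifnot(ncol(counts) == 2L)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (any(colSums(counts) == 0)) {
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                n_rows = nrow(counts), reason = "zero_column"))
  }
  if (nrow(counts) < 2L) {
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                n_rows = nrow(counts), reason = "degenerate"))
  }
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  stat <- sum((counts - expected)^2 / expected)
  df <- nrow(counts) - 1L
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       n_rows = nrow(counts), reason = "")
}

#' Delta-Pi: top-two same-direction change in percent isoform
#'
#' Per-isoform deltas are `Pi_i(A) - Pi_i(B)`. The positive candidate is the
#' sum of the (up to) two largest positive deltas, the negative candidate the
#' absolute sum of the two most negative; the larger magnitude wins and its
#' sign is kept (ties go to the positive direction). The contributing
#' isoform(s) are returned with their individual deltas.
#'
#' @param counts isoform x 2 count matrix (uncollapsed), rows named by
#'   isoform key.
#' @param min_contrib smallest per-isoform |delta| still reported as a
#'   contributor (default 0: up to two are always reported when nonzero).
#' @return list with `dpi` (signed), `contributors` (data.frame `key`,
#'   `delta`, at most two rows); `dpi` is `NA` if either column sum is zero.
#' @export
delta_pi <- function(counts, min_contrib = 0) {
  stopifnot(ncol(counts) == 2L)
  tot <- colSums(counts)
  if (any(tot == 0)) return(list(dpi = NA_real_, contributors = NULL))
  delta <- counts[, 1L] / tot[1L] - counts[, 2L] / tot[2L]
  keys <- rownames(counts) %||% as.character(seq_along(delta))
  pos <- sort(delta[delta > 0], decreasing = TRUE)
  neg <- sort(delta[delta < 0])
  dpi_pos <- sum(head(pos, 2L))
  dpi_neg <- -sum(head(neg, 2L))
  if (dpi_pos >= dpi_neg) {
    dpi <- dpi_pos
    sel <- head(order(-delta), 2L)
    sel <- sel[delta[sel] > min_contrib]
  } else {
    dpi <- -dpi_neg
    sel <- head(order(delta), 2L)
    sel <- sel[delta[sel] < -min_contrib]
  }
  contributors <- if (length(sel)) {
    data.frame(key = keys[sel], delta = unname(delta[sel]))
  } else NULL
  list(dpi = dpi, contributors = contributors)
}

#' Benjamini-Hochberg / Benjamini-Yekutieli step-up adjustment
#'
#' Standard step-up with monotonicity enforcement; `adjust_by()` additionally
#' multiplies by `c(m) = sum(1/i)`. Each test's correction factor
#' (adjusted / raw before clamping at 1) is returned alongside the clamped
#' adjusted p-values.
#'
#' @param p vector of p-values in `[0, 1]` (NA allowed, passed through).
#' @return list with `adjusted` (clamped at 1) and `factor` (pre-clamping
#'   adjusted / raw).
#' @export
adjust_bh <- function(p) step_up(p, cm = 1)

#' @rdname adjust_bh
#' @export
adjust_by <- function(p) {
  m <- sum(!is.na(p))
  step_up(p, cm = sum(1 / seq_len(m)))
}

step_up <- function(p, cm) {
  ok <- !is.na(p)
  m <- sum(ok)
  adjusted <- factor <- rep(NA_real_, length(p))
  if (m == 0L) return(list(adjusted = adjusted, factor = factor))
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  raw_sorted <- pv[o]
  ranks <- m:1
  pre <- cummin(cm * m / ranks * raw_sorted)[ro]
  adjusted[ok] <- pmin(pre, 1)
  factor[ok] <- pre / pv
  list(adjusted = adjusted, factor = factor)
}

#' Gene-level differential isoform / TSS / polyA usage test
#'
#' For each gene with at least `min_depth` reads in **each** of the two
#' groups, the per-feature counts are collapsed to at most a `(k+1) x 2`
#' table ([collapse_top_k()]), tested with [chi2_nx2()], and the effect size
#' delta-Pi is computed on the *uncollapsed* per-feature proportions
#' ([delta_pi()]). Raw p-values are BH-adjusted across all testable genes of
#' the comparison. A gene is significant when `adj_p <= fdr` and
#' `|dpi| >= min_dpi`.
#'
#' @param csmm CSMM table.
#' @param group two-level labels aligned with `csmm` rows (`NA` = excluded);
#'   the first level (alphabetical, or of a factor's levels) is group A.
#' @param feature `"isoform"`, `"tss"` or `"polya"`.
#' @param min_depth minimum reads per gene per group (default 25).
#' @param k isoform rows kept before collapsing (default 10).
#' @param fdr,min_dpi significance thresholds (defaults 0.05 and 0.1).
#' @param key_mode see [isoform_key()].
#' @return a `die_result` data.table: per gene `feature, n_features, total_a,
#'   total_b, statistic, raw_p, adj_p, correction_factor, dpi, iso1,
#'   iso1_dpi, iso2, iso2_dpi, testable, reason, significant`.
#' @export
die_test <- function(csmm, group, feature = c("isoform", "tss", "polya"),
                     min_depth = 25L, k = 10L, fdr = 0.05, min_dpi = 0.1,
                     key_mode = "peaks") {
  feature <- match.arg(feature)
  group <- as.factor(group)
  lev <- levels(droplevels(group))
  if (length(lev) != 2L) stop("exactly two groups required, got: ",
                              paste(lev, collapse = ", "))
  ut <- build_usage_tables(csmm, as.character(group), feature, key_mode)
  die_test_usage(ut, lev, min_depth = min_depth, k = k, fdr = fdr,
                 min_dpi = min_dpi, feature = feature)
}

#' Gene-level usage test from precomputed usage tables
#'
#' Same contract as [die_test()] but starting from [build_usage_tables()]
#' output (useful with the counts-level simulator).
#'
#' @param ut a `usage_tables` object.
#' @param groups character vector of the two group labels `c(A, B)`.
#' @inheritParams die_test
#' @return a `die_result` data.table (see [die_test()]).
#' @export
die_test_usage <- function(ut, groups, min_depth = 25L, k = 10L, fdr = 0.05,
                           min_dpi = 0.1, feature = attr(ut, "feature") %||% "isoform") {
  stopifnot(length(groups) == 2L)
  ut <- as.data.table(ut)[group %in% groups]
  genes <- sort(unique(ut$gene_id))
  rows <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    m <- usage_matrix(ut, genes[i], groups)
    tot <- colSums(m)
    row <- data.table(gene_id = genes[i], feature = feature,
                      n_features = nrow(m), total_a = tot[1L], total_b = tot[2L],
                      statistic = NA_real_, raw_p = NA_real_,
                      dpi = NA_real_, iso1 = NA_character_, iso1_dpi = NA_real_,
                      iso2 = NA_character_, iso2_dpi = NA_real_,
                      testable = FALSE, reason = "")
    if (any(tot < min_depth)) {
      row$reason <- "depth"
    } else {
      ct <- chi2_nx2(collapse_top_k(m, k))
      if (is.na(ct$p)) {
        row$reason <- ct$reason
      } else {
        dp <- delta_pi(m)
        row[, `:=`(statistic = ct$statistic, raw_p = ct$p, dpi = dp$dpi,
                   testable = TRUE)]
        cn <- dp$contributors
        if (!is.null(cn) && nrow(cn) >= 1L) {
          row[, `:=`(iso1 = cn$key[1L], iso1_dpi = cn$delta[1L])]
        }
        if (!is.null(cn) && nrow(cn) >= 2L) {
          row[, `:=`(iso2 = cn$key[2L], iso2_dpi = cn$delta[2L])]
        }
      }
    }
    rows[[i]] <- row
  }
  res <- rbindlist(rows)
  adj <- adjust_bh(ifelse(res$testable, res$raw_p, NA_real_))
  res[, `:=`(adj_p = adj$adjusted, correction_factor = adj$factor)]
  res[, significant := testable & !is.na(adj_p) & adj_p <= fdr & abs(dpi) >= min_dpi]
  setcolorder(res, c("gene_id", "feature", "n_features", "total_a", "total_b",
                     "statistic", "raw_p", "adj_p", "correction_factor", "dpi",
                     "iso1", "iso1_dpi", "iso2", "iso2_dpi", "testable",
                     "reason", "significant"))
  setattr(res, "class", c("die_result", class(res)))
  res[]
}

#' @export
print.die_result <- function(x, ...) {
  n_test <- sum(x$testable)
  n_sig <- sum(x$significant)
  cat("<die_result> ", x$feature[1L], " test: ", nrow(x), " genes, ", n_test,
      " testable, ", n_sig, " significant",
      if (n_test > 0) paste0(" (", percent_label(n_sig, n_test), ")"), "\n",
      sep = "")
  invisible(x)
}

#' Exon-level 2x2 differential inclusion test
#'
#' Per exon, a 2x2 inclusion/exclusion by group table. Exons are skipped as
#' constitutive unless the pooled Psi (both groups combined) lies in
#' `psi_range`, and must satisfy the expected-count criterion
#' `min(rowSums) * min(colSums) / total >= min_expected`. P-values from
#' [chi2_nx2()] are BY-adjusted (dependent tests); significance requires
#' `adj_p <= fdr` and `|dpsi| >= min_dpsi`.
#'
#' @param psi a `psi_table` ([psi_tables()]).
#' @param groups the two group labels `c(A, B)`.
#' @param fdr,min_dpsi significance thresholds (defaults 0.05, 0.1).
#' @param psi_range pooled-Psi testability window (default `c(0.1, 0.9)`).
#' @param min_expected expected-count eligibility threshold (default 5).
#' @return an `exon_test_result` data.table: per exon `psi_a, psi_b, dpsi,
#'   statistic, raw_p, adj_p, correction_factor, testable, reason,
#'   significant`.
#' @export
exon_test <- function(psi, groups, fdr = 0.05, min_dpsi = 0.1,
                      psi_range = c(0.1, 0.9), min_expected = 5) {
  stopifnot(length(groups) == 2L)
  dp <- delta_psi(psi, groups[1L], groups[2L])
  res <- dp[, .(exon_id, psi_a, psi_b, dpsi, incl_a, excl_a, incl_b, excl_b)]
  res[, `:=`(statistic = NA_real_, raw_p = NA_real_, testable = FALSE, reason = "")]
  for (i in seq_len(nrow(res))) {
    m <- matrix(c(res$incl_a[i], res$excl_a[i], res$incl_b[i], res$excl_b[i]),
                nrow = 2L, dimnames = list(c("incl", "excl"), groups))
    pooled <- sum(m[1L, ]) / sum(m)
    if (!is.finite(pooled) || pooled < psi_range[1L] || pooled > psi_range[2L]) {
      res[i, reason := "constitutive"]
      next
    }
    crit <- min(rowSums(m)) * min(colSums(m)) / sum(m)
    if (crit < min_expected) {
      res[i, reason := "expected_counts"]
      next
    }
    ct <- chi2_nx2(m)
    if (is.na(ct$p)) {
      res[i, reason := ct$reason]
    } else {
      res[i, `:=`(statistic = ct$statistic, raw_p = ct$p, testable = TRUE)]
    }
  }
  adj <- adjust_by(ifelse(res$testable, res$raw_p, NA_real_))
  res[, `:=`(adj_p = adj$adjusted, correction_factor = adj$factor)]
  res[, significant := testable & !is.na(adj_p) & adj_p <= fdr &
        !is.na(dpsi) & abs(dpsi) >= min_dpsi]
  setattr(res, "class", c("exon_test_result", class(res)))
  res[]
}

#' @export
print.exon_test_result <- function(x, ...) {
  cat("<exon_test_result> ", nrow(x), " exons, ", sum(x$testable),
      " testable, ", sum(x$significant), " significant\n", sep = "")
  invisible(x)
}

#' Build two-group labels from sample/hierarchy-node membership
#'
#' A read belongs to a group when its `cell_type` is a leaf under the group's
#' hierarchy node (reads with `NA` cell type belong only to the root group)
#' and, if given, its `sample` matches.
#'
#' @param csmm CSMM table (optionally with a `sample` column).
#' @param cellmap a `cell_type_map`.
#' @param a,b group specifications: a node name, or `list(node =, sample =,
#'   label =)`.
#' @return character vector of labels (`NA` for reads in neither group).
#' @export
make_groups <- function(csmm, cellmap, a, b) {
  csmm <- as.data.table(csmm)
  spec <- function(g) if (is.character(g)) list(node = g, sample = NULL, label = g) else g
  a <- spec(a); b <- spec(b)
  member <- function(s) {
    m <- if (s$node == cellmap$root) rep(TRUE, nrow(csmm))
         else csmm$cell_type %in% hierarchy_leaves(cellmap, s$node)
    if (!is.null(s$sample)) m <- m & csmm$sample == s$sample
    m
  }
  ma <- member(a); mb <- member(b)
  if (any(ma & mb)) stop("groups overlap; choose disjoint nodes/samples")
  la <- a$label %||% paste0(a$sample %||% "", a$node)
  lb <- b$label %||% paste0(b$sample %||% "", b$node)
  out <- rep(NA_character_, nrow(csmm))
  out[ma] <- la
  out[mb] <- lb
  out
}
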