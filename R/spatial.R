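# Cross-platform exon selection and directional concordance of delta-Psi
# between single-cell and spatial long-read data.

#' Per-exon read-match statistics for eligibility filtering
#'
#' For each exon: `n_overlap`, the number of calls from reads overlapping the
#' exon with exonic sequence (included or discarded calls; excluded reads skip
#' the exon by an intron), and `n_exact`, the number of reads whose junctions
#' match this exact exon (included calls).
#'
#' @param calls result of [call_exons()].
#' @return data.table: `exon_id, overlapping, n_overlap, n_exact`.
#' @export
exon_match_stats <- function(calls) {
  calls <- as.data.table(calls)
  calls[, .(overlapping = overlapping[1L],
            n_overlap = sum(status != "excluded"),
            n_exact = sum(status == "included")), by = exon_id]
}

#' Exons eligible for cross-platform comparison
#'
#' Exons without alternative donor/acceptor variants (not `overlapping`) pass
#' unconditionally; flagged exons pass only when strictly more than
#' `min_frac` of their overlapping reads match the exact exon.
#'
#' @param stats result of [exon_match_stats()] (columns `exon_id`,
#'   `overlapping`, `n_overlap`, `n_exact`).
#' @param min_frac strict lower bound on the exact-match fraction
#'   (default 0.9).
#' @return character vector of eligible exon ids.
#' @export
eligible_exons <- function(stats, min_frac = 0.9) {
  stats <- as.data.table(stats)
  ok <- !stats$overlapping |
    (stats$n_overlap > 0L & stats$n_exact / stats$n_overlap > min_frac)
  stats$exon_id[ok]
}

#' Directional concordance of delta-Psi between two platforms
#'
#' Pairs exons present in both inputs with a defined delta-Psi that is
#' nonzero in at least one platform. An exon counts as same-sign only when
#' both deltas are nonzero with equal sign (a zero on either side is
#' discordant). Reports the same-sign fraction, the exact symmetric-binomial
#' point probability `C(n, k) 0.5^n` for the same-sign count, and the Pearson
#' correlation of the paired deltas.
#'
#' @param dpsi_sc,dpsi_spatial named numeric vectors of delta-Psi keyed by
#'   exon id (e.g. from [delta_psi()]).
#' @return a `concordance_report` list: `n`, `n_same_sign`,
#'   `fraction_same_sign`, `point_binomial_p`, `pearson_r`, `r_squared`,
#'   `exons` (data.table of the pairs).
#' @export
concordance <- function(dpsi_sc, dpsi_spatial) {
  ids <- intersect(names(dpsi_sc), names(dpsi_spatial))
  a <- dpsi_sc[ids]; b <- dpsi_spatial[ids]
  keep <- !is.na(a) & !is.na(b) & (a != 0 | b != 0)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  same <- sign(a) == sign(b) & a != 0 & b != 0
  k <- sum(same)
  r <- if (n >= 2L) stats::cor(a, b) else NA_real_
  structure(list(
    n = n, n_same_sign = k,
    fraction_same_sign = if (n > 0) k / n else NA_real_,
    point_binomial_p = if (n > 0) binom_point_prob(k, n) else NA_real_,
    pearson_r = r, r_squared = r^2,
    exons = data.table(exon_id = names(a), dpsi_sc = unname(a),
                       dpsi_spatial = unname(b), same_sign = same)),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report> ", x$n_same_sign, "/", x$n, " exons same direction (",
      if (x$n > 0) percent_label(x$n_same_sign, x$n) else "NA",
      "), binomial point p = ", format(x$point_binomial_p, digits = 3),
      ", r^2 = ", format(x$r_squared, digits = 3), "\n", sep = "")
  invisible(x)
}
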