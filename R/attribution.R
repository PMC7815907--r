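# Tracing parent-level DIE through the cell-type hierarchy: delta-Pi ratios,
# the three-model classification (Single-Cell-Type / Both-Cell-Types /
# No-Cell-Type), traceability, concurrence enrichment, and TSS directionality.

#' Classify one gene's parent-level DIE against its two child cell types
#'
#' A child "participates" when it is testable, `|dpi_child| >= dpi_threshold`,
#' and its delta-Pi points in the same direction as the parent's. Both
#' participating children give the Both-Cell-Types model, exactly one the
#' Single-Cell-Type model, none (with both testable) the No-Cell-Type model;
#' if a child is untestable and the other does not participate the gene is
#' `insufficient-depth`. Ratios are `dpi_child / dpi_parent` on magnitudes
#' with matched sign (opposite-sign changes get negative ratios and never
#' explain the parent).
#'
#' @param parent_dpi the parent comparison's delta-Pi (|parent_dpi| must be
#'   `>= dpi_threshold` for the model to be defined).
#' @param child_dpi numeric length-2 (named) vector of child delta-Pi values
#'   (`NA` allowed).
#' @param child_testable logical length-2.
#' @param dpi_threshold participation threshold (default 0.1).
#' @return list with `model` (one of `"Single-Cell-Type"`, `"Both-Cell-Types"`,
#'   `"No-Cell-Type"`, `"insufficient-depth"`, or `NA` when the parent effect
#'   is below threshold), `ratios`, `responsible` (names of participating
#'   children).
#' @export
classify_model <- function(parent_dpi, child_dpi, child_testable,
                           dpi_threshold = 0.1) {
  stopifnot(length(child_dpi) == 2L, length(child_testable) == 2L)
  nm <- names(child_dpi) %||% c("child1", "child2")
  if (is.na(parent_dpi) || abs(parent_dpi) < dpi_threshold) {
    return(list(model = NA_character_, ratios = setNames(c(NA_real_, NA_real_), nm),
                responsible = character(0)))
  }
  ratios <- setNames(if (parent_dpi == 0) rep(NA_real_, 2L) else
    sign(parent_dpi) * child_dpi / abs(parent_dpi), nm)
  part <- child_testable & !is.na(child_dpi) &
    abs(child_dpi) >= dpi_threshold & sign(child_dpi) == sign(parent_dpi)
  model <- if (sum(part) == 2L) "Both-Cell-Types"
  else if (sum(part) == 1L) "Single-Cell-Type"
  else if (all(child_testable)) "No-Cell-Type"
  else "insufficient-depth"
  list(model = model, ratios = ratios, responsible = nm[part])
}

#' Classify all parent-significant genes across a hierarchy split
#'
#' @param parent_res `die_result` for the parent comparison.
#' @param child_res named list of exactly two `die_result`s, one per child.
#' @param dpi_threshold participation threshold (default 0.1).
#' @param parent_genes optional restriction (default: parent testable genes
#'   with `|dpi| >= dpi_threshold`).
#' @return an `attribution` data.table: per gene `parent_dpi`,
#'   `dpi_<child>`, `ratio_<child>`, `model`, `responsible`.
#' @export
attribute_die <- function(parent_res, child_res, dpi_threshold = 0.1,
                          parent_genes = NULL) {
  stopifnot(length(child_res) == 2L)
  nm <- names(child_res) %||% c("child1", "child2")
  pr <- as.data.table(parent_res)
  genes <- parent_genes %||% pr[testable == TRUE & abs(dpi) >= dpi_threshold, gene_id]
  c1 <- as.data.table(child_res[[1L]]); c2 <- as.data.table(child_res[[2L]])
  out <- data.table(gene_id = genes,
                    parent_dpi = pr$dpi[match(genes, pr$gene_id)])
  i1 <- match(genes, c1$gene_id); i2 <- match(genes, c2$gene_id)
  d1 <- c1$dpi[i1]; d2 <- c2$dpi[i2]
  t1 <- !is.na(i1) & c1$testable[i1]; t2 <- !is.na(i2) & c2$testable[i2]
  res <- lapply(seq_along(genes), function(i) {
    classify_model(out$parent_dpi[i], setNames(c(d1[i], d2[i]), nm),
                   c(t1[i], t2[i]), dpi_threshold)
  })
  out[, paste0("dpi_", nm) := .(d1, d2)]
  out[, paste0("ratio_", nm) := .(vapply(res, function(r) r$ratios[1L], numeric(1)),
                                  vapply(res, function(r) r$ratios[2L], numeric(1)))]
  out[, model := vapply(res, function(r) r$model, character(1))]
  out[, responsible := vapply(res, function(r) paste(r$responsible, collapse = ","),
                              character(1))]
  setattr(out, "class", c("attribution", class(out)))
  out[]
}

#' Model-class proportions with binomial standard errors
#'
#' @param attribution result of [attribute_die()].
#' @return data.table of model classes with counts, percentages and `se_pct`
#'   (the standard error of the proportion, in percentage points).
#' @export
model_summary <- function(attribution) {
  at <- as.data.table(attribution)[!is.na(model)]
  n <- nrow(at)
  s <- at[, .(count = .N), by = model]
  s[, pct := 100 * count / n]
  s[, se_pct := 100 * vapply(count / n, function(p) proportion_se(p, n)$se, numeric(1))]
  s[]
}

#' Traceability of bulk DIE to individual leaf cell types
#'
#' A bulk-significant gene is `traced` when some leaf cell type has
#' `dpi_leaf / dpi_bulk >= ratio_threshold` with matching sign; `low-depth`
#' when no leaf is testable; otherwise `untraced`.
#'
#' @param bulk_res `die_result` for the bulk comparison (significant genes
#'   are assessed).
#' @param leaf_res named list of `die_result`s, one per leaf cell type.
#' @param ratio_threshold default 0.9.
#' @return data.table: `gene_id, bulk_dpi, max_ratio, status`.
#' @export
traceability <- function(bulk_res, leaf_res, ratio_threshold = 0.9) {
  br <- as.data.table(bulk_res)[significant == TRUE]
  out <- data.table(gene_id = br$gene_id, bulk_dpi = br$dpi,
                    max_ratio = NA_real_, status = "low-depth")
  for (i in seq_len(nrow(out))) {
    g <- out$gene_id[i]; bd <- out$bulk_dpi[i]
    ratios <- vapply(leaf_res, function(lr) {
      lr <- as.data.table(lr)
      j <- match(g, lr$gene_id)
      if (is.na(j) || !lr$testable[j] || is.na(lr$dpi[j])) return(NA_real_)
      sign(bd) * lr$dpi[j] / abs(bd)
    }, numeric(1))
    if (all(is.na(ratios))) next
    out[i, max_ratio := max(ratios, na.rm = TRUE)]
    out[i, status := if (max_ratio >= ratio_threshold) "traced" else "untraced"]
  }
  out[]
}

#' Concurrence of DIE across two sibling cell types
#'
#' Over genes testable in both children, counts how often `|dpi| >=
#' dpi_threshold` holds in both, compares with the expectation under
#' independence (product of marginals), and tests association with Fisher's
#' two-sided exact test on the 2x2 gene table.
#'
#' @param res1,res2 `die_result`s for the two children (same comparison axis).
#' @param dpi_threshold default 0.1.
#' @return list: `n`, `observed_pct`, `expected_pct`, `ratio`, `fisher_p`,
#'   `table`.
#' @export
concurrence_test <- function(res1, res2, dpi_threshold = 0.1) {
  r1 <- as.data.table(res1)[testable == TRUE]
  r2 <- as.data.table(res2)[testable == TRUE]
  genes <- intersect(r1$gene_id, r2$gene_id)
  if (length(genes) < 1L) stop("no genes testable in both children")
  x1 <- abs(r1$dpi[match(genes, r1$gene_id)]) >= dpi_threshold
  x2 <- abs(r2$dpi[match(genes, r2$gene_id)]) >= dpi_threshold
  tab <- table(factor(x1, c(TRUE, FALSE)), factor(x2, c(TRUE, FALSE)))
  observed <- 100 * mean(x1 & x2)
  expected <- 100 * mean(x1) * mean(x2)
  list(n = length(genes), observed_pct = observed, expected_pct = expected,
       ratio = if (expected > 0) observed / expected else NA_real_,
       fisher_p = fisher.test(tab)$p.value, table = tab)
}

#' Directionality of focal-group-specific TSS choice
#'
#' For genes where the focal group's dominant TSS differs from the dominant
#' TSS of the other groups, counts how many focal TSSs lie upstream
#' (strand-aware: smaller coordinate on `+`, larger on `-`) and reports both
#' the exact symmetric-binomial point probability `C(n, k) 0.5^n` and the
#' one-sided tail.
#'
#' @param tss data.frame with columns `gene_id`, `strand`, `focal_tss`,
#'   `other_tss` (genomic TSS coordinates). Genes with identical coordinates
#'   are excluded from `n`.
#' @return list: `n_upstream`, `n`, `point_p`, `tail_p`.
#' @export
tss_directionality <- function(tss) {
  tss <- as.data.table(tss)
  tss <- tss[focal_tss != other_tss]
  up <- ifelse(tss$strand == "-", tss$focal_tss > tss$other_tss,
               tss$focal_tss < tss$other_tss)
  k <- sum(up); n <- length(up)
  list(n_upstream = k, n = n,
       point_p = binom_point_prob(k, n),
       tail_p = binom_tail_prob(k, n))
}

#' Standard error and 95% CI of a proportion
#'
#' `SE = sqrt(p(1-p)/n)`; the Wald interval `p +/- 1.96 SE` is clamped to
#' `[0, 1]`.
#'
#' @param p_hat estimated proportion in `[0, 1]`.
#' @param n sample size (>= 1).
#' @return list: `se`, `lower`, `upper`.
#' @export
proportion_se <- function(p_hat, n) {
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 1)
  se <- sqrt(p_hat * (1 - p_hat) / n)
  list(se = se, lower = max(0, p_hat - 1.96 * se), upper = min(1, p_hat + 1.96 * se))
}
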