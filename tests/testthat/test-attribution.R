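test_that("model classification follows the participation rules", {
  single <- classify_model(0.20, c(n = 0.19, g = 0.01), c(TRUE, TRUE))
  expect_equal(single$model, "Single-Cell-Type")
  expect_equal(unname(single$ratios["n"]), 0.95)
  expect_equal(single$responsible, "n")

  both <- classify_model(0.20, c(n = 0.15, g = 0.12), c(TRUE, TRUE))
  expect_equal(both$model, "Both-Cell-Types")

  none <- classify_model(0.12, c(n = 0.05, g = 0.04), c(TRUE, TRUE))
  expect_equal(none$model, "No-Cell-Type")

  lowdepth <- classify_model(0.20, c(n = NA, g = 0.04), c(FALSE, TRUE))
  expect_equal(lowdepth$model, "insufficient-depth")

  # opposite-sign child never participates
  opp <- classify_model(0.20, c(n = -0.25, g = 0.15), c(TRUE, TRUE))
  expect_equal(opp$model, "Single-Cell-Type")
  expect_equal(opp$responsible, "g")

  # parent effect below threshold -> undefined
  expect_true(is.na(classify_model(0.05, c(n = 0.2, g = 0.2), c(TRUE, TRUE))$model))
})

test_that("attribution partitions parent-significant genes and sums to one", {
  mk <- function(genes, dpi, testable = TRUE) {
    structure(data.table::data.table(gene_id = genes, dpi = dpi,
                                     testable = testable, significant = testable),
              class = c("die_result", "data.table", "data.frame"))
  }
  parent <- mk(sprintf("g%d", 1:5), c(0.3, 0.2, 0.15, 0.12, 0.05))
  kids <- list(neurons = mk(sprintf("g%d", 1:5), c(0.29, 0.02, 0.14, 0.03, 0.2)),
               glia = mk(sprintf("g%d", 1:5), c(0.01, 0.19, 0.13, 0.04, 0.2)))
  at <- attribute_die(parent, kids)
  expect_equal(nrow(at), 4L)   # g5 is below the parent threshold
  expect_equal(at$model, c("Single-Cell-Type", "Single-Cell-Type",
                           "Both-Cell-Types", "No-Cell-Type"))
  ms <- model_summary(at)
  expect_equal(sum(ms$pct), 100)
})

test_that("traceability splits genes into traced / untraced / low-depth", {
  mk <- function(dpi, testable) {
    structure(data.table::data.table(gene_id = c("g1", "g2", "g3"), dpi = dpi,
                                     testable = testable,
                                     significant = c(TRUE, TRUE, TRUE)),
              class = c("die_result", "data.table", "data.frame"))
  }
  bulk <- mk(c(0.2, 0.2, 0.2), c(TRUE, TRUE, TRUE))
  leaves <- list(
    EN = mk(c(0.19, 0.10, NA), c(TRUE, TRUE, FALSE)),
    IN = mk(c(0.04, 0.12, NA), c(TRUE, TRUE, FALSE)))
  tr <- traceability(bulk, leaves)
  expect_equal(tr$status, c("traced", "untraced", "low-depth"))
  expect_equal(tr$max_ratio[1], 0.95)
})

test_that("concurrence matches the enumeration oracle on a fixed gene table", {
  mk <- function(dpi) {
    structure(data.table::data.table(gene_id = sprintf("g%02d", seq_along(dpi)),
                                     dpi = dpi, testable = TRUE),
              class = c("die_result", "data.table", "data.frame"))
  }
  # 80 genes: 30 concurrent, 10 child1-only, 10 child2-only, 30 neither
  d1 <- c(rep(0.2, 30), rep(0.2, 10), rep(0.01, 10), rep(0.01, 30))
  d2 <- c(rep(0.2, 30), rep(0.01, 10), rep(0.2, 10), rep(0.01, 30))
  ct <- concurrence_test(mk(d1), mk(d2))
  expect_equal(ct$n, 80L)
  expect_equal(ct$observed_pct, 100 * 30 / 80)
  expect_equal(ct$expected_pct, 100 * 0.5 * 0.5)
  expect_equal(ct$ratio, 1.5)

  # oracle: hypergeometric enumeration of the two-sided exact test
  tab <- matrix(c(30, 10, 10, 30), 2)
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  ks <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  pv <- stats::dhyper(ks, cs[1], N - cs[1], rs[1])
  pobs <- stats::dhyper(tab[1, 1], cs[1], N - cs[1], rs[1])
  oracle <- sum(pv[pv <= pobs * (1 + 1e-7)])
  expect_equal(oracle, 1.487480e-05, tolerance = 1e-6)
  expect_equal(ct$fisher_p, oracle, tolerance = 1e-9)
})

test_that("independently generated children show no concurrence enrichment", {
  set.seed(77)
  reps <- replicate(40, {
    d1 <- ifelse(runif(200) < 0.5, 0.2, 0.01)
    d2 <- ifelse(runif(200) < 0.5, 0.2, 0.01)
    mk <- function(dpi) structure(
      data.table::data.table(gene_id = sprintf("g%03d", 1:200), dpi = dpi,
                             testable = TRUE),
      class = c("die_result", "data.table", "data.frame"))
    ct <- concurrence_test(mk(d1), mk(d2))
    c(ct$ratio, ct$fisher_p)
  })
  expect_equal(mean(reps[1, ]), 1, tolerance = 0.1)
  expect_lt(mean(reps[2, ] < 0.05), 0.2)   # no systematic enrichment
})

test_that("TSS directionality is strand-aware with exact binomial statistics", {
  # minus-strand gene: larger coordinate is upstream
  tss <- data.frame(gene_id = c("g1", "g2", "g3"),
                    strand = c("-", "+", "+"),
                    focal_tss = c(5000, 100, 300),
                    other_tss = c(4000, 200, 300))
  td <- tss_directionality(tss)
  expect_equal(td$n, 2L)            # identical-TSS gene excluded
  expect_equal(td$n_upstream, 2L)
  expect_equal(td$tail_p, 0.5^2)    # k = n -> tail is 0.5^n

  k34 <- tss_directionality(data.frame(
    gene_id = sprintf("g%02d", 1:40), strand = "+",
    focal_tss = c(rep(1, 34), rep(9, 6)), other_tss = 5))
  expect_equal(k34$point_p, 3.490986e-06, tolerance = 1e-6)

  k70 <- tss_directionality(data.frame(
    gene_id = sprintf("g%02d", 1:93), strand = "+",
    focal_tss = c(rep(1, 70), rep(9, 23)), other_tss = 5))
  expect_equal(k70$point_p, 3.771889e-07, tolerance = 1e-6)
  expect_equal(k70$tail_p, 5.513128e-07, tolerance = 1e-6)
})

test_that("proportion SE follows the closed form with boundary behavior", {
  expect_equal(proportion_se(0.5, 100)$se, 0.05)
  expect_equal(proportion_se(0.75, 350)$se, 0.02314550, tolerance = 1e-6)
  expect_equal(proportion_se(0, 50)$se, 0)
  expect_equal(proportion_se(1, 50)$se, 0)
  ci <- proportion_se(0.99, 20)
  expect_lte(ci$upper, 1)
})

test_that("planted single-child effects classify as Single-Cell-Type", {
  attribute_sim <- function(cfg, seed) {
    sim <- simulate_dataset(cfg, seed)
    pr <- process_reads(sim$reads, sim$genes, sim$genome, sim$cage, sim$polya,
                        sim$cellmap, tolerance = cfg$tolerance)
    two <- function(node) {
      grp <- make_groups(pr$csmm, sim$cellmap,
                         list(node = node, sample = "HIPP", label = "A"),
                         list(node = node, sample = "PFC", label = "B"))
      die_test(pr$csmm, grp)
    }
    at <- attribute_die(two("bulk"), list(neurons = two("neurons"),
                                          nonneurons = two("nonneurons")))
    die <- sim$truth$die_genes[sim$truth$die_genes$true_dpi > 0, ]$gene_id
    at[at$gene_id %in% die, ]
  }

  # zero-noise limit: attribution is exact
  cfg0 <- sim_config(n_genes = 10, n_die_genes = 6, die_dpi = 0.3,
                     die_cell_types = c("EN", "IN"), depth = 100,
                     exact_counts = TRUE)
  at0 <- attribute_sim(cfg0, seed = 42)
  expect_equal(nrow(at0), 6L)
  expect_true(all(at0$model == "Single-Cell-Type"))
  expect_true(all(at0$responsible == "neurons"))

  # sampled reads: the responsible child dominates, the sibling's spurious
  # top-two delta-Pi can occasionally cross the 0.1 threshold
  cfg1 <- sim_config(n_genes = 15, n_die_genes = 8, die_dpi = 0.3,
                     die_cell_types = c("EN", "IN"), depth = 250,
                     truncation_rate = 0)
  at1 <- attribute_sim(cfg1, seed = 42)
  expect_gt(nrow(at1), 0)
  expect_true(all(at1$model %in% c("Single-Cell-Type", "Both-Cell-Types")))
  expect_gte(mean(at1$model == "Single-Cell-Type"), 0.85)
  expect_true(all(grepl("(^|,)neurons", at1$responsible)))
})
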