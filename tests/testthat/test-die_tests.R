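test_that("chi-square statistic matches the closed form and is row-order invariant", {
  m <- matrix(c(30, 10, 10, 30), 2)
  ct <- chi2_nx2(m)
  expect_equal(ct$statistic, 20.0)
  expect_equal(ct$p, 7.744216e-06, tolerance = 1e-6)

  flat <- chi2_nx2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  set.seed(31)
  m3 <- matrix(rpois(12, 20), ncol = 2)
  perm <- m3[sample(nrow(m3)), ]
  expect_equal(chi2_nx2(m3)$p, chi2_nx2(perm)$p)

  # zero column -> untestable; all-zero rows are dropped first
  expect_true(is.na(chi2_nx2(matrix(c(5, 5, 0, 0), 2))$p))
  withzero <- rbind(m, c(0, 0))
  expect_equal(chi2_nx2(withzero)$statistic, 20.0)
  expect_equal(chi2_nx2(withzero)$df, 1L)
})

test_that("2x2 chi-square equals N(ad-bc)^2/(row and column products) to 1e-9", {
  set.seed(7)
  for (i in 1:200) {
    m <- matrix(rpois(4, 25) + 1, 2)
    a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]; n <- sum(m)
    ref <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(chi2_nx2(m)$statistic, ref, tolerance = 1e-9)
  }
})

test_that("chi-square p agrees with the stats reference without continuity correction", {
  set.seed(11)
  for (i in 1:50) {
    m <- matrix(rpois(10, 15) + 1, ncol = 2)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    ct <- chi2_nx2(m)
    expect_equal(ct$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ct$p, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("delta-Pi sums the top two same-direction changes", {
  m1 <- rbind(c(50, 20), c(30, 30), c(20, 50))
  d1 <- delta_pi(m1)
  expect_equal(d1$dpi, 0.3)
  expect_equal(nrow(d1$contributors), 1L)

  m2 <- rbind(c(40, 25), c(40, 25), c(10, 25), c(10, 25))
  d2 <- delta_pi(m2)
  expect_equal(d2$dpi, 0.3)
  expect_equal(sort(d2$contributors$delta), c(0.15, 0.15))

  expect_equal(delta_pi(rbind(c(10, 10), c(10, 10)))$dpi, 0)
  expect_true(is.na(delta_pi(rbind(c(0, 5), c(0, 5)))$dpi))

  # negative direction dominates and keeps its sign
  m3 <- rbind(c(30, 10), c(30, 10), c(30, 10), c(5, 35), c(5, 35))
  d3 <- delta_pi(m3)
  expect_equal(d3$dpi, -0.6)
  expect_equal(d3$contributors$delta, c(-0.3, -0.3))
})

test_that("BH and BY step-ups match the worked arithmetic", {
  bh <- adjust_bh(c(0.01, 0.02, 0.03))
  expect_equal(bh$adjusted, c(0.03, 0.03, 0.03))
  by <- adjust_by(c(0.01, 0.02, 0.03))
  expect_equal(by$adjusted, c(0.055, 0.055, 0.055))

  # a raw p of 1.7e-4 at rank 5 of 78 carries a BH factor of 78/5 = 15.6
  p <- c(1e-6, 2e-6, 3e-6, 4e-6, 1.7e-4, rep(0.5, 73))
  res <- adjust_bh(p)
  expect_equal(res$factor[5], 15.6)
  expect_equal(signif(res$adjusted[5], 2), 2.7e-3)
})

test_that("BH/BY match the independent step-up reference on 1000 random vectors", {
  set.seed(97)
  for (i in 1:1000) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p)$adjusted, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(adjust_by(p)$adjusted, p.adjust(p, "BY"), tolerance = 1e-12)
  }
})

test_that("usage test enforces the per-group depth rule", {
  ut <- data.table::rbindlist(list(
    data.table::data.table(gene_id = "G1", group = c("A", "A", "B", "B"),
                           count = c(15L, 10L, 13L, 12L))[
                             , key := c("i1", "i2", "i1", "i2")],
    data.table::data.table(gene_id = "G2", group = c("A", "A", "B", "B"),
                           count = c(15L, 9L, 13L, 12L))[
                             , key := c("i1", "i2", "i1", "i2")]))
  data.table::setattr(ut, "class", c("usage_tables", class(ut)))
  res <- die_test_usage(ut, c("A", "B"), min_depth = 25L)
  expect_true(res[res$gene_id == "G1"]$testable)     # 25/25
  expect_false(res[res$gene_id == "G2"]$testable)    # 24/25
  expect_equal(res[res$gene_id == "G2"]$reason, "depth")
})

test_that("significance needs both the FDR and the effect-size threshold", {
  # large counts, tiny effect: p is small but |dpi| < 0.1
  ut <- data.table::data.table(
    gene_id = "G1", group = rep(c("A", "B"), each = 2),
    count = c(5200L, 4800L, 4800L, 5200L))[, key := rep(c("i1", "i2"), 2)]
  data.table::setattr(ut, "class", c("usage_tables", class(ut)))
  res <- die_test_usage(ut, c("A", "B"))
  expect_lt(res$adj_p, 0.05)
  expect_lt(abs(res$dpi), 0.1)
  expect_false(res$significant)
})

test_that("exon test eligibility and constitutive windows follow the criteria", {
  pt <- data.table::data.table(
    exon_id = rep(c("e_ok", "e_small", "e_const"), each = 2),
    group = rep(c("A", "B"), 3),
    incl = c(5L, 5L, 1L, 1L, 19L, 19L),
    excl = c(5L, 5L, 1L, 16L, 1L, 1L))
  pt[, psi := incl / (incl + excl)]
  data.table::setattr(pt, "class", c("psi_table", class(pt)))
  res <- exon_test(pt, c("A", "B"))
  # min(rowSums) * min(colSums) / total = 10 * 10 / 20 = 5 -> eligible
  expect_true(res[res$exon_id == "e_ok"]$testable)
  # 2 * 2 / 19 < 5 -> ineligible
  expect_false(res[res$exon_id == "e_small"]$testable)
  expect_equal(res[res$exon_id == "e_small"]$reason, "expected_counts")
  # pooled psi 0.95 -> constitutive
  expect_false(res[res$exon_id == "e_const"]$testable)
  expect_equal(res[res$exon_id == "e_const"]$reason, "constitutive")
})

test_that("power rises with depth and the null keeps nominal size (counts level)", {
  set.seed(515)
  null <- simulate_usage(n_genes = 600, dpi = 0, depth = c(100, 100))
  rn <- die_test_usage(null$ut, c("A", "B"))
  expect_gt(mean(rn$raw_p[rn$testable] < 0.05), 0.02)
  expect_lt(mean(rn$raw_p[rn$testable] < 0.05), 0.08)

  pw <- sapply(c(25, 100), function(d) {
    set.seed(515 + d)
    s <- simulate_usage(n_genes = 250, dpi = 0.3, depth = c(d, d))
    mean(die_test_usage(s$ut, c("A", "B"))$significant)
  })
  expect_lt(pw[1], pw[2])
  expect_gte(pw[2], 0.8)
})
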