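make_cm <- function(counts, cond) {
  count_matrix(counts, gene_ids = sprintf("g%d", seq_len(nrow(counts))),
               sample_ids = sprintf("s%d", seq_len(ncol(counts))),
               condition = cond)
}

test_that("median-of-ratios size factors match the hand computation", {
  m <- make_cm(matrix(c(10, 30, 50, 20, 60, 100), 3, 2), c("A", "B"))
  sf <- estimate_size_factors(m)
  # geometric-mean reference, ratios all sqrt(1/2) and sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  ident <- make_cm(matrix(rep(c(5, 9, 13), 2), 3, 2), c("A", "B"))
  expect_equal(unname(estimate_size_factors(ident)), c(1, 1))
  single <- make_cm(matrix(c(5, 9, 13), 3, 1), "A")
  expect_equal(unname(estimate_size_factors(single)), 1)
  zero <- make_cm(matrix(c(0, 3, 5, 0), 2, 2), c("A", "B"))
  expect_error(estimate_size_factors(zero), "nonzero")
})

test_that("log2 fold change uses the pseudocount estimator", {
  cnt <- rbind(c(10, 10, 10, 80, 80, 80),
               c(100, 100, 100, 100, 100, 100))
  m <- make_cm(cnt, rep(c("A", "B"), each = 3))
  m$size_factors <- rep(1, 6)
  de <- test_differential(m, "A", "B")
  expect_equal(de$log2fc[1], log2(80.5 / 10.5), tolerance = 1e-12)
  expect_equal(de$log2fc[2], 0)
})

test_that("all-zero genes are reported as uninformative nonDE", {
  cnt <- rbind(c(0, 0, 0, 0, 0, 0), c(50, 60, 55, 90, 100, 95),
               c(40, 45, 50, 45, 40, 50))
  m <- make_cm(cnt, rep(c("A", "B"), each = 3))
  de <- test_differential(m, "A", "B")
  expect_equal(de$p[1], 1)
  expect_equal(de$call[1], "nonDE")
  expect_error(test_differential(m, "A", "C"), "condition")
})

test_that("fold changes are invariant to rescaling a sample with its size factor", {
  set.seed(21)
  cnt <- matrix(rnbinom(100 * 6, size = 20, mu = 100), 100, 6)
  m <- make_cm(cnt, rep(c("A", "B"), each = 3))
  sf <- estimate_size_factors(m)
  de1 <- test_differential(m, "A", "B")
  m2 <- m
  m2$counts[, 3] <- m$counts[, 3] * 4
  m2$size_factors <- sf * c(1, 1, 4, 1, 1, 1)
  de2 <- test_differential(m2, "A", "B")
  expect_equal(de2$log2fc, de1$log2fc, tolerance = 1e-12)
})

test_that("BH adjustment matches the brute-force step-up reference", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(31)
  for (i in 1:1000) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("type-I error is calibrated under the NB null", {
  fr <- vapply(1:2, function(s) {
    set.seed(s)
    cnt <- matrix(rnbinom(2000 * 6, size = 1 / 0.05, mu = 500), 2000, 6)
    m <- make_cm(cnt, rep(c("A", "B"), each = 3))
    mean(test_differential(m, "A", "B")$p < 0.05)
  }, numeric(1))
  expect_gt(mean(fr), 0.035)
  expect_lt(mean(fr), 0.065)
})

test_that("detection rate rises with the simulated effect size", {
  # 30 of 300 genes shifted; the null majority anchors the size factors
  set.seed(41)
  rates <- vapply(c(0, 0.5, 1, 2), function(lfc) {
    mu_b <- c(rep(200 * 2^lfc, 30), rep(200, 270))
    cnt <- cbind(matrix(rnbinom(300 * 3, size = 20, mu = 200), 300, 3),
                 matrix(rnbinom(300 * 3, size = 20, mu = mu_b), 300, 3))
    m <- make_cm(cnt, rep(c("A", "B"), each = 3))
    mean(test_differential(m, "A", "B")$call[1:30] != "nonDE")
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], 0.9)
})

test_that("overlap summary counts same-direction calls and correlates fold changes", {
  de <- function(ids, calls, lfc) data.frame(gene_id = ids, log2fc = lfc,
                                             p = 0.01, fdr = 0.01,
                                             call = calls,
                                             stringsAsFactors = FALSE)
  a <- de(c("g1", "g2", "g3", "g4"), c("UP", "UP", "UP", "DOWN"), c(1, 2, 3, -2))
  b <- de(c("g1", "g2", "g3", "g4"), c("nonDE", "UP", "UP", "UP"), c(0.1, 2, 3, 2))
  ov <- overlap_de(a, b)
  expect_equal(ov$n_up_both, 2)
  expect_equal(ov$n_down_both, 0)
  expect_equal(ov$n_up_a, 3)
  self <- overlap_de(a, a)
  expect_equal(self$fc_correlation, 1)
  disj <- overlap_de(a, de(c("g9"), "UP", 1))
  expect_equal(disj$n_up_both, 0)
  expect_null(disj$fc_correlation)
})

test_that("induction-pattern matching selects UP-then-DOWN genes only", {
  d1 <- data.frame(gene_id = c("a", "b", "c"), call = c("UP", "UP", "nonDE"))
  d2 <- data.frame(gene_id = c("a", "b", "c"), call = c("DOWN", "UP", "DOWN"))
  expect_equal(match_induction_pattern(d1, d2), "a")
})

test_that("cold-responsiveness is the OR over DE tables", {
  d1 <- data.frame(gene_id = c("a", "b"), call = c("nonDE", "nonDE"))
  d2 <- data.frame(gene_id = c("a", "b"), call = c("UP", "nonDE"))
  r <- classify_cold_responsive(list(d1, d2))
  expect_true(r[["a"]])
  expect_false(r[["b"]])
  expect_false(any(classify_cold_responsive(list(d1, d1))))
})

test_that("responsive fraction on synthetic truth matches the designed fraction", {
  sim <- simulate_genome(300, seed = 17)
  cm <- simulate_counts(sim$truth, seed = 18)
  de3 <- test_differential(cm, "22C", "4C_3h")
  de12 <- test_differential(cm, "22C", "4C_12h")
  resp <- classify_cold_responsive(list(de3, de12))
  designed <- mean(sim$truth$de_3h != "nonDE" | sim$truth$de_12h != "nonDE")
  # binomial-scale agreement around the designed responsive fraction
  expect_lt(abs(mean(resp) - designed), 3 * sqrt(designed * (1 - designed) / 300) + 0.02)
})

test_that("rank-sum test: exact enumeration on small groups", {
  v <- stats::setNames(1:6, letters[1:6])
  r <- compare_gene_classes(v, letters[1:3], letters[4:6])
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact enumeration")
  # symmetric data sit at U = n1*n2/2 with p near 1
  v2 <- stats::setNames(c(1, 2, 3, 1, 2, 3), letters[1:6])
  r2 <- compare_gene_classes(v2, letters[1:3], letters[4:6])
  expect_equal(r2$U, 4.5)
  expect_gt(r2$p, 0.9)
})

test_that("exact and approximate branches agree and match wilcox.test", {
  set.seed(61)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, 0, 1.5))
    v <- stats::setNames(c(x, y), sprintf("g%d", 1:16))
    ex <- compare_gene_classes(v, sprintf("g%d", 1:8), sprintf("g%d", 9:16))
    ap <- compare_gene_classes(v, sprintf("g%d", 1:8), sprintf("g%d", 9:16),
                               exact_max = 0)
    expect_lt(abs(ex$p - ap$p), 0.02)
    wt <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ex$U, unname(wt$statistic))
    expect_equal(ex$p, wt$p.value, tolerance = 1e-12)
  }
  # heavy ties at tiny n: the enumeration handles them; the approximation
  # is only loosely close that far from its asymptotic regime
  vt <- stats::setNames(c(1, 2, 2, 3, 2, 3, 3, 4), sprintf("t%d", 1:8))
  et <- compare_gene_classes(vt, sprintf("t%d", 1:4), sprintf("t%d", 5:8))
  at <- compare_gene_classes(vt, sprintf("t%d", 1:4), sprintf("t%d", 5:8),
                             exact_max = 0)
  expect_lt(abs(et$p - at$p), 0.15)
})
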