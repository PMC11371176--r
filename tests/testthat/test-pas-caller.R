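test_that("all-zero tracks yield no units", {
  tr <- toy_tracks(numeric(500), numeric(500))
  expect_equal(nrow(detect_units(tr$plus, tr$minus)), 0)
})

test_that("a minus-strand block reports its 5' end at the right edge", {
  v <- numeric(500); v[101:400] <- 5
  tr <- toy_tracks(numeric(500), v)
  u <- detect_units(tr$plus, tr$minus, min_signal = 1, min_len = 200)
  expect_equal(nrow(u), 1)
  expect_equal(u$start, 100)
  expect_equal(u$end, 400)
  expect_equal(u$strand, "-")
  expect_equal(u$tss, 399)
  expect_equal(u$mean_signal, 5)
})

test_that("gap bridging depends on max_gap", {
  v <- numeric(500); v[101:200] <- 2; v[211:310] <- 2  # 10-base internal gap
  tr <- toy_tracks(v, numeric(500))
  merged <- detect_units(tr$plus, tr$minus, min_signal = 1, min_len = 50,
                         max_gap = 20)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(100, 310))
  split <- detect_units(tr$plus, tr$minus, min_signal = 1, min_len = 50,
                        max_gap = 5)
  expect_equal(nrow(split), 2)
})

test_that("segmentation matches a brute-force scanner on random tracks", {
  set.seed(101)
  for (case in 1:300) {
    n <- sample(200:2000, 1)
    v <- rpois(n, lambda = sample(c(0.3, 0.8, 2), 1))
    ms <- sample(1:3, 1); ml <- sample(c(5, 20, 60), 1); mg <- sample(c(0, 3, 15), 1)
    tr <- toy_tracks(v, numeric(n))
    got <- detect_units(tr$plus, tr$minus, min_signal = ms, min_len = ml,
                        max_gap = mg)
    want <- brute_segment(v, ms, ml, mg)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("raising min_signal never increases the bases covered by units", {
  # unit COUNT is not monotone in the threshold (a plateau with a dip splits
  # into two units when the dip drops below it), but with no gap bridging or
  # length filter the covered bases shrink monotonically
  set.seed(55)
  v <- rpois(3000, 1.5)
  tr <- toy_tracks(v, numeric(3000))
  covered <- vapply(1:5, function(ms) {
    u <- detect_units(tr$plus, tr$minus, min_signal = ms, min_len = 1,
                      max_gap = 0)
    sum(u$end - u$start)
  }, numeric(1))
  expect_true(all(diff(covered) <= 0))
})

test_that("plus-strand boundary geometry follows the 3'-half / 20% rule", {
  g <- gene_model("g", "chr1", 1000, 2000, "+")[1, ]
  # L = 1000: 3'-half [1500, 2000), downstream [2000, 2200)
  expect_equal(classify_pas(g, 1600, "-")$window_hit, "3prime_half")
  expect_equal(classify_pas(g, 1500, "-")$window_hit, "3prime_half")
  expect_false(classify_pas(g, 1499, "-")$is_pas)
  expect_equal(classify_pas(g, 1999, "-")$window_hit, "3prime_half")
  expect_equal(classify_pas(g, 2000, "-")$window_hit, "downstream_20pct")
  expect_equal(classify_pas(g, 2199, "-")$window_hit, "downstream_20pct")
  expect_false(classify_pas(g, 2200, "-")$is_pas)
  expect_error(classify_pas(g, 1600, "+"), "antisense")
})

test_that("minus-strand windows mirror the plus-strand case", {
  g <- gene_model("g", "chr1", 1000, 2000, "-")[1, ]
  # mirror: 3'-half [1000, 1500), downstream [800, 1000)
  expect_equal(classify_pas(g, 1200, "+")$window_hit, "3prime_half")
  expect_equal(classify_pas(g, 1000, "+")$window_hit, "3prime_half")
  expect_false(classify_pas(g, 1500, "+")$is_pas)
  expect_equal(classify_pas(g, 999, "+")$window_hit, "downstream_20pct")
  expect_equal(classify_pas(g, 800, "+")$window_hit, "downstream_20pct")
  expect_false(classify_pas(g, 799, "+")$is_pas)
})

test_that("reflection oracle: minus-strand decisions equal reflected plus-strand ones", {
  set.seed(77)
  ref <- 10000L
  for (i in 1:200) {
    s <- sample(1000:4000, 1); L <- sample(1:1500, 1)
    gp <- gene_model("g", "chr1", s, s + L, "+")[1, ]
    pos <- sample((s - 800):(s + L + 800), 1)
    want <- classify_pas(gp, pos, "-")
    gm <- gene_model("g", "chr1", ref - (s + L), ref - s, "-")[1, ]
    got <- classify_pas(gm, ref - 1L - pos, "+")
    expect_identical(got, want)
  }
})

test_that("degenerate one-base gene still classifies via the ceiling rule", {
  g <- gene_model("g", "chr1", 1000, 1001, "+")[1, ]
  # L = 1: 3'-half [1001, 1001) empty, downstream [1001, 1002) width 1
  expect_equal(classify_pas(g, 1001, "-")$window_hit, "downstream_20pct")
  expect_false(classify_pas(g, 1000, "-")$is_pas)
  expect_false(classify_pas(g, 1002, "-")$is_pas)
})

test_that("no units means no PAS genes; strongest unit wins with leftmost ties", {
  genes <- gene_model("g", "chr1", 1000, 2000, "+")
  empty <- detect_units(toy_tracks(numeric(10), numeric(10))$plus,
                        toy_tracks(numeric(10), numeric(10))$minus)
  expect_false(call_pas_genes(genes, empty)$is_pas)
  units <- data.frame(
    chrom = "chr1", strand = "-",
    start = c(1400, 1500), end = c(1710, 1810),
    tss = c(1709, 1809), mean_signal = c(3, 7), stringsAsFactors = FALSE)
  call <- call_pas_genes(genes, units)
  expect_true(call$is_pas)
  expect_equal(call$unit_mean_signal, 7)
  expect_equal(call$as_tss, 1809)
  ties <- within(units, mean_signal <- c(7, 7))
  expect_equal(call_pas_genes(genes, ties)$as_tss, 1709)
  # same-strand units are never antisense candidates
  sense <- within(units, strand <- "+")
  expect_false(call_pas_genes(genes, sense)$is_pas)
})

test_that("PAS calls survive genome reflection", {
  sim <- simulate_genome(60, seed = 13)
  cov <- simulate_nascent_coverage(sim$genes, sim$truth, sim$chrom_len,
                                   seed = 13)
  calls <- call_pas_genes(sim$genes,
                          detect_units(cov$plus, cov$minus))
  len <- sim$chrom_len
  rgenes <- reflect_genes(sim$genes, len)
  rplus <- coverage_track("chrS", "+", rev(cov$minus$values))
  rminus <- coverage_track("chrS", "-", rev(cov$plus$values))
  rcalls <- call_pas_genes(rgenes, detect_units(rplus, rminus))
  expect_identical(rcalls$is_pas, calls$is_pas)
  expect_identical(rcalls$window_hit, calls$window_hit)
})
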