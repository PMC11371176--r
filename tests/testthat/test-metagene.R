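test_that("anchor arithmetic is strand-aware", {
  genes <- gene_model(c("p", "m"), "chrT", c(1000, 1500), c(1400, 2001),
                      c("+", "-"))
  a0 <- make_plus1_anchors(genes, offset = 0)
  expect_equal(a0$anchor, genes$tss)
  a150 <- make_plus1_anchors(genes, offset = 150)
  expect_equal(a150$anchor, c(1150, 1850))
  expect_error(make_plus1_anchors(genes, window = 250, bin = 7), "divisible")
})

test_that("constant coverage gives an all-ones anchored matrix", {
  genes <- gene_model("g", "chrT", 400, 900, "+")
  tr <- toy_tracks(rep(1, 2000), rep(1, 2000))
  m <- anchored_matrix(tr$plus, tr$minus,
                       make_plus1_anchors(genes, offset = 150))
  expect_equal(dim(m$matrix), c(1, 50))
  expect_true(all(m$matrix == 1))
})

test_that("minus-strand rows equal the reversed plus-strand computation", {
  set.seed(91)
  v <- rpois(4000, 2)
  genes_p <- gene_model("g", "chrT", 1000, 2000, "+")
  genes_m <- gene_model("g", "chrT", 2000, 3000, "-")
  # full genome reflection: the minus gene is the mirror image of the plus one
  w <- rev(v)
  tr <- list(plus = coverage_track("chrT", "+", v),
             minus = coverage_track("chrT", "-", w))
  mp <- anchored_matrix(tr$plus, tr$minus, make_plus1_anchors(genes_p))
  mm <- anchored_matrix(tr$plus, tr$minus, make_plus1_anchors(genes_m))
  expect_equal(unname(mm$matrix), unname(mp$matrix))
})

test_that("bin = 1 anchored rows equal direct per-base slices", {
  set.seed(92)
  v <- rpois(5000, 3); w <- rpois(5000, 3)
  tr <- list(plus = coverage_track("chrT", "+", v),
             minus = coverage_track("chrT", "-", w))
  for (i in 1:50) {
    s <- sample(500:4000, 1)
    strand <- sample(c("+", "-"), 1)
    g <- gene_model("g", "chrT", s, s + 600, strand)
    a <- make_plus1_anchors(g, offset = 150, window = 100, bin = 1)
    m <- anchored_matrix(tr$plus, tr$minus, a)
    anc <- a$anchor[1]
    want <- if (strand == "+") v[(anc - 100 + 1):(anc + 100)]
            else rev(w[(anc - 100 + 2):(anc + 100 + 1)])
    expect_equal(unname(m$matrix[1, ]), want)
  }
})

test_that("anchors near the chromosome edge are excluded, not padded", {
  genes <- gene_model(c("edge", "ok"), "chrT", c(0, 1000), c(500, 1600),
                      "+")
  tr <- toy_tracks(rep(1, 2000), rep(1, 2000))
  m <- anchored_matrix(tr$plus, tr$minus,
                       make_plus1_anchors(genes, offset = 0, window = 250))
  expect_equal(m$excluded, "edge")
  expect_equal(rownames(m$matrix), "ok")
})

test_that("scaled-body binning uses the left-heavy remainder partition", {
  genes <- gene_model("g", "chrT", 0, 10, "+")
  tr <- toy_tracks(as.numeric(1:10), numeric(10))
  m <- scaled_body_matrix(tr$plus, tr$minus, genes, nbins = 3)
  # partitions of 4, 3, 3 bases
  expect_equal(unname(m$widths[1, ]), c(4, 3, 3))
  expect_equal(unname(m$matrix[1, ]), c(mean(1:4), mean(5:7), mean(8:10)))
  const <- toy_tracks(rep(2.5, 10), numeric(10))
  mc <- scaled_body_matrix(const$plus, const$minus, genes, nbins = 5)
  expect_true(all(mc$matrix == 2.5))
})

test_that("scaled-body profiles conserve per-gene total signal", {
  set.seed(93)
  sim <- simulate_genome(30, seed = 93)
  cov <- simulate_nascent_coverage(sim$genes, sim$truth, sim$chrom_len,
                                   seed = 93)
  m <- scaled_body_matrix(cov$plus, cov$minus, sim$genes, nbins = 40)
  for (r in seq_len(nrow(m$matrix))) {
    g <- sim$genes[sim$genes$gene_id == rownames(m$matrix)[r], ]
    v <- if (g$strand == "+") cov$plus$values else cov$minus$values
    total <- sum(v[(g$start + 1):g$end])
    expect_equal(sum(m$matrix[r, ] * m$widths[r, ]), total,
                 tolerance = 1e-12)
  }
})

test_that("profiles are identical after genome reflection", {
  sim <- simulate_genome(40, seed = 94)
  cov <- simulate_nascent_coverage(sim$genes, sim$truth, sim$chrom_len,
                                   seed = 94)
  len <- sim$chrom_len
  rgenes <- reflect_genes(sim$genes, len)
  rplus <- coverage_track("chrS", "+", rev(cov$minus$values))
  rminus <- coverage_track("chrS", "-", rev(cov$plus$values))
  sb <- scaled_body_matrix(cov$plus, cov$minus, sim$genes)
  rsb <- scaled_body_matrix(rplus, rminus, rgenes)
  expect_identical(rsb$matrix, sb$matrix)
  am <- anchored_matrix(cov$plus, cov$minus, make_plus1_anchors(sim$genes))
  ram <- anchored_matrix(rplus, rminus, make_plus1_anchors(rgenes))
  expect_identical(ram$matrix, am$matrix)
})

test_that("profile summaries report 95% confidence bands", {
  m <- structure(list(matrix = matrix(rep(1:4, 5), 4, 5), mode = "anchored"),
                 class = "profile_matrix")
  s <- profile_summary(m)
  expect_equal(s$mean, rep(2.5, 5))
  expect_equal(s$ci_hi - s$mean, rep(1.96 * sd(1:4) / 2, 5))
  ident <- structure(list(matrix = matrix(3, 4, 5), mode = "anchored"),
                     class = "profile_matrix")
  expect_true(all(profile_summary(ident)$ci_hi == 3))
  single <- structure(list(matrix = matrix(3, 1, 5), mode = "anchored"),
                      class = "profile_matrix")
  s1 <- profile_summary(single)
  expect_true(attr(s1, "degenerate"))
  expect_equal(s1$ci_lo, s1$ci_hi)
  # Monte-Carlo half-width for Gaussian rows, n = 400, sd = 1
  set.seed(95)
  hw <- replicate(30, {
    g <- structure(list(matrix = matrix(rnorm(400 * 3), 400, 3),
                        mode = "anchored"), class = "profile_matrix")
    s <- profile_summary(g)
    mean(s$ci_hi - s$mean)
  })
  expect_lt(abs(mean(hw) - 1.96 / sqrt(400)) / (1.96 / sqrt(400)), 0.1)
})
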