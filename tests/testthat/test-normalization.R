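test_that("size factors match the median-of-ratios hand computation", {
  counts <- matrix(c(2, 4, 6, 4, 8, 12), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("A", "B")))
  f <- size_factors(counts)
  # gene geometric means (2.828, 5.657, 8.485); all per-sample ratios constant
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  norm <- sweep(counts, 2, f, "/")
  expect_equal(norm[, "A"], norm[, "B"], tolerance = 1e-12)
})

test_that("identical samples get unit size factors", {
  counts <- matrix(rep(c(5, 10, 20), 3), nrow = 3,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(counts)), rep(1, 3), tolerance = 1e-12)
})

test_that("scaling one sample's counts scales its factor relative to the others", {
  # size factors are defined up to a common constant, so the invariant is on
  # factor ratios: sample 2's factor gains the full scale against every other
  # sample, and the normalized counts are unchanged
  for (seed in 1:5) {
    set.seed(seed)
    counts <- matrix(rpois(40, 100) + 1, nrow = 10,
                     dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
    f0 <- size_factors(counts)
    c2 <- counts
    scale_by <- 3.5
    c2[, 2] <- counts[, 2] * scale_by
    f1 <- size_factors(c2)
    expect_equal(f1[2] / f1[-2], scale_by * f0[2] / f0[-2],
                 tolerance = 1e-10)
    # normalized counts are unchanged up to one common constant
    norm0 <- sweep(counts, 2, f0, "/")
    norm1 <- sweep(c2, 2, f1, "/")
    ratio <- norm1 / norm0
    expect_lt(max(ratio) / min(ratio) - 1, 1e-10)
  }
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  counts <- matrix(rnbinom(600, mu = 150, size = 20), nrow = 100,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  counts[3, 2] <- 0   # exercise the all-positive reference restriction
  mine <- size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("a matrix with no all-positive gene is an error", {
  counts <- matrix(c(0, 5, 5, 0), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("A", "B")))
  expect_error(size_factors(counts), "no gene has nonzero counts")
})

test_that("per-kb expression reproduces the worked arithmetic in both variants", {
  gt <- gene_table("g1", "cyanobacterium", 500L)
  counts <- matrix(10, 1, 2, dimnames = list("g1", c("A", "B")))
  factors <- c(A = 1, B = 1)
  perkb <- per_kb_expression(counts, factors, gt, variant = "per-kb")
  expect_equal(unname(perkb["g1", ]), c(20, 20))
  # with a normalized library total forced to 1e6 the scaled value is also 20
  gt2 <- gene_table(c("g1", "g2"), rep("cyanobacterium", 2), c(500L, 1000L))
  counts2 <- rbind(g1 = c(10, 10), g2 = c(1e6 - 10, 1e6 - 10))
  colnames(counts2) <- c("A", "B")
  scaled <- per_kb_expression(counts2, factors, gt2, variant = "scaled")
  expect_equal(unname(scaled["g1", ]), c(20, 20), tolerance = 1e-12)
})

test_that("scaled expression is invariant to per-sample count scaling", {
  gt <- toy_gene_table()
  counts <- toy_counts()
  e0 <- per_kb_expression(counts, size_factors(counts), gt)
  doubled <- counts
  doubled[, 1] <- doubled[, 1] * 2L
  e1 <- per_kb_expression(doubled, size_factors(doubled), gt)
  expect_equal(e1, e0, tolerance = 1e-10)
})

test_that("condition means average replicates arithmetically", {
  des <- toy_design()
  counts <- toy_counts()
  counts[1, condition_samples(des, "A")] <- c(10L, 20L)
  counts[1, condition_samples(des, "B")] <- c(1L, 2L)
  cm <- condition_means(counts, des)
  expect_equal(cm["cy1", "A"], 15)
  expect_equal(cm["cy1", "B"], 1.5)
  # quadruplicate
  des4 <- steady_state_design(data.frame(
    label = c("A", "B", "C", "D", "E"),
    irradiance = c(100, 500, 1000, 1000, 1000),
    pO2 = c(0, 0, 0, 0.3, 0.6),
    n_replicates = c(4L, 2L, 2L, 2L, 2L)))
  m <- matrix(0, 1, 12, dimnames = list("g", des4$sample_map$sample_id))
  m[1, condition_samples(des4, "A")] <- 1:4
  expect_equal(condition_means(m, des4)["g", "A"], 2.5)
})

test_that("the gene filters implement the zero-condition and <15 rules strictly", {
  des <- toy_design()
  counts <- toy_counts()
  counts[] <- 100L
  counts[1, condition_samples(des, "C")] <- 0L   # zero in one condition
  gt <- toy_gene_table()
  expr <- matrix(100, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  expr[2, ] <- 14.99
  expr[3, ] <- 15.0
  rep <- filter_genes(counts, expr, des)
  expect_false("cy1" %in% rep$kept)     # zero-count condition
  expect_false("cy2" %in% rep$kept)     # mean 14.99 < 15
  expect_true("cy3" %in% rep$kept)      # mean exactly 15 is kept
  expect_equal(rep$n_removed_zero_condition, 1)
  expect_equal(rep$n_removed_low_expression, 1)
  expect_equal(rep$n_input - rep$n_removed_zero_condition -
                 rep$n_removed_low_expression, length(rep$kept))
})

test_that("filtering is idempotent", {
  des <- toy_design()
  counts <- toy_counts()
  gt <- toy_gene_table()
  expr <- per_kb_expression(counts, size_factors(counts), gt)
  rep1 <- filter_genes(counts, expr, des)
  rep2 <- filter_genes(counts[rep1$kept, , drop = FALSE],
                       expr[rep1$kept, , drop = FALSE], des)
  expect_equal(rep2$n_removed_zero_condition, 0)
  expect_equal(rep2$n_removed_low_expression, 0)
  expect_identical(rep2$kept, rep1$kept)
})

test_that("variance mask drops exactly floor(fraction * n) lowest-variance genes", {
  for (n in c(3, 7, 10, 23)) {
    for (f in c(0, 0.30, 0.5, 0.9)) {
      set.seed(n * 100 + round(f * 10))
      prof <- matrix(rnorm(n * 3), n, 3,
                     dimnames = list(sprintf("g%02d", 1:n), NULL))
      kept <- variance_mask(prof, f)
      expect_length(kept, n - floor(f * n))
    }
  }
})

test_that("zero-variance profiles are masked first and ties break by gene id", {
  prof <- rbind(
    flat1 = c(1, 1, 1), flat2 = c(2, 2, 2),
    varied1 = c(1, 5, 2), varied2 = c(0, 3, 9), varied3 = c(2, 8, 1),
    varied4 = c(5, 1, 4), varied5 = c(3, 3, 9), varied6 = c(1, 2, 6),
    varied7 = c(9, 2, 2), varied8 = c(4, 9, 1)
  )
  kept <- variance_mask(prof, 0.30)   # 3 of 10 dropped
  expect_length(kept, 7)
  expect_false(any(c("flat1", "flat2") %in% kept))
  # identical-variance tie: lexicographically smaller id is dropped first
  tie <- rbind(a_gene = c(1, 2, 1), b_gene = c(1, 2, 1),
               c1 = c(0, 9, 0), c2 = c(9, 0, 9), c3 = c(0, 0, 9))
  kept_tie <- variance_mask(tie, 0.2)  # drop exactly one
  expect_false("a_gene" %in% kept_tie)
  expect_true("b_gene" %in% kept_tie)
})

test_that("reference scaling divides by the lowest-treatment value", {
  expect_equal(normalize_profile(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(normalize_profile(c(5, 5, 5)), c(1, 1, 1))
  expect_error(normalize_profile(c(0, 4, 8)), "zero")
  m <- rbind(g1 = c(10, 20, 30), g2 = c(0, 4, 8))
  expect_error(normalize_profile(m), "g2")
})

test_that("log-mean-centering matches arithmetic and obeys Jensen", {
  expect_equal(log_mean_center(c(2, 2, 2)), c(0, 0, 0))
  expect_equal(log_mean_center(c(1, 2, 4)),
               log2(c(3 / 7, 6 / 7, 12 / 7)), tolerance = 1e-12)
  expect_error(log_mean_center(c(1, 0, 2)), "positive")
  for (seed in 1:20) {
    set.seed(seed)
    x <- exp(rnorm(5))
    s <- sum(log_mean_center(x))
    expect_lte(s, 1e-12)
  }
  expect_equal(sum(log_mean_center(rep(3.7, 4))), 0)
})
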