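test_that("responsive calls apply the pseudocounted two-fold rule at the extremes", {
  cm <- rbind(g_up = c(10, 7, 25),     # (25.5)/(10.5) = 2.4286 -> up
              g_near = c(10, 15, 19.9),  # below threshold
              g_down = c(20, 12, 10),  # (10.5)/(20.5) = 0.512 -> none
              g_down2 = c(20.5, 12, 10))  # (10.5)/(21) = 0.5 exactly -> down
  colnames(cm) <- c("L", "M", "H")
  calls <- call_responsive(cm, c("L", "M", "H"), axis = "irradiance")
  expect_equal(calls$fold_change[1], 25.5 / 10.5, tolerance = 1e-12)
  expect_equal(calls$direction, c("up", "none", "none", "down"))
  expect_equal(calls$responsive, c(TRUE, FALSE, FALSE, TRUE))
  # interior conditions are ignored
  cm2 <- cm
  cm2[, "M"] <- 1e6
  calls2 <- call_responsive(cm2, c("L", "M", "H"), axis = "irradiance")
  expect_equal(calls2$responsive, calls$responsive)
})

test_that("swapping the axis extremes mirrors direction and keeps the flag", {
  set.seed(11)
  cm <- matrix(runif(60, 0, 100), 20, 3,
               dimnames = list(sprintf("g%02d", 1:20), c("L", "M", "H")))
  fwd <- call_responsive(cm, c("L", "M", "H"), axis = "pO2")
  rev <- call_responsive(cm, c("H", "M", "L"), axis = "pO2")
  expect_equal(fwd$responsive, rev$responsive)
  map <- c(up = "down", down = "up", none = "none")
  expect_equal(unname(map[fwd$direction]), rev$direction)
  expect_equal(fwd$fold_change, 1 / rev$fold_change, tolerance = 1e-12)
})

test_that("responsive tallies split by species, axis and direction", {
  gt <- toy_gene_table()
  calls <- data.frame(
    gene_id = c("cy1", "cy2", "he1", "he2", "cy3"),
    axis = c("irradiance", "irradiance", "irradiance", "pO2", "pO2"),
    fold_change = c(3, 0.4, 2.5, 5, 1.2),
    direction = c("up", "down", "up", "up", "none"),
    responsive = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  tab <- count_responsive(calls, gt)
  get_n <- function(sp, ax, dir) {
    r <- tab[tab$species == sp & tab$axis == ax & tab$direction == dir, "n"]
    if (length(r)) r else 0L
  }
  expect_equal(get_n("cyanobacterium", "irradiance", "any"), 2L)
  expect_equal(get_n("cyanobacterium", "irradiance", "up"), 1L)
  expect_equal(get_n("cyanobacterium", "irradiance", "down"), 1L)
  expect_equal(get_n("heterotroph", "pO2", "any"), 1L)
  expect_equal(get_n("cyanobacterium", "pO2", "any"), 0L)
  empty <- count_responsive(calls[calls$responsive == FALSE & FALSE, ], gt)
  expect_equal(nrow(empty), 0)
})

test_that("differential testing finds planted fold changes and nothing in nulls", {
  des <- default_design()
  tc <- truth_config(n_genes_cyano = 400L, n_genes_het = 0L,
                     planted_responsive = data.frame(
                       culture = "binary", species = "cyanobacterium",
                       axis = c("irradiance", "pO2"), n = c(40L, 0L)))
  for (seed in 1:3) {
    genes <- make_genomes(tc, seed = seed)
    sim <- simulate_expression(genes, des, tc, seed = seed)
    expr <- per_kb_expression(sim$counts, size_factors(sim$counts), genes)
    res <- test_differential(expr, des, "LL-LO", "HL-LO")
    truth <- sim$truth[match(res$gene_id, sim$truth$gene_id), ]
    expect_true(all(res$significant[truth$responsive_irradiance]))
    flat <- truth$shape_irradiance == "flat"
    expect_true(all(!res$significant[flat]))
  }
})

test_that("identical replicate sets give log2FC 0 and no significance", {
  des <- toy_design()
  expr <- matrix(rep(c(50, 80, 20, 100, 10, 60), 10), nrow = 6,
                 dimnames = list(toy_gene_table()$gene_id,
                                 des$sample_map$sample_id))
  res <- suppressWarnings(test_differential(expr, des, "A", "B"))
  expect_equal(res$log2fc, rep(0, 6))
  expect_true(all(!res$significant))
})

test_that("adjusted p values are monotone in the raw p ranking", {
  des <- default_design()
  tc <- truth_config(n_genes_cyano = 300L, n_genes_het = 0L,
                     planted_responsive = data.frame(
                       culture = "binary", species = "cyanobacterium",
                       axis = "irradiance", n = 30L))
  genes <- make_genomes(tc, seed = 4)
  sim <- simulate_expression(genes, des, tc, seed = 4)
  expr <- per_kb_expression(sim$counts, size_factors(sim$counts), genes)
  for (method in c("moderated", "welch")) {
    res <- test_differential(expr, des, "ML-LO", "HL-MO", method = method)
    ord <- order(res$p)
    expect_true(all(diff(res$p_adj[ord]) >= -1e-15))
    expect_true(all(res$p_adj >= res$p - 1e-15))
    expect_true(all(res$p_adj <= 1))
  }
})

test_that("differential testing requires two replicates per condition", {
  des <- toy_design()
  expr <- matrix(50, 6, 10, dimnames = list(toy_gene_table()$gene_id,
                                            des$sample_map$sample_id))
  expect_error(test_differential(expr[, -1], des, "A", "B"), ">= 2")
})
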