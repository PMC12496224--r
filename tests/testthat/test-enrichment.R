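test_that("single-member worked example gives score 2 at any alpha", {
  v <- c(g1 = 9, g2 = 5, g3 = 2, g4 = 1)
  s <- gene_set("top", "g1")
  for (a in c(0, 0.25, 1, 2))
    expect_equal(ssgsea_sample_score(v, s, alpha = a), 2.0)
})

test_that("ssGSEA equals the brute-force ECDF-difference oracle", {
  v <- withr::with_seed(21, stats::setNames(rnorm(8), paste0("g", 1:8)))
  sets <- unlist(lapply(1:3, function(k)
    utils::combn(names(v), k, simplify = FALSE)), recursive = FALSE)
  for (alpha in c(0, 0.25, 1)) {
    for (mem in sets[seq(1, length(sets), by = 3)]) {
      expect_equal(ssgsea_sample_score(v, gene_set("s", mem), alpha),
                   brute_ssgsea(v, mem, alpha), tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA is rank-based: monotone transforms and identical vectors", {
  v <- withr::with_seed(4, stats::setNames(rnorm(30, 5, 2), sprintf("g%02d", 1:30)))
  s <- gene_set("s", sprintf("g%02d", c(2, 9, 17, 25)))
  base <- ssgsea_sample_score(v, s)
  expect_equal(ssgsea_sample_score(exp(v), s), base)
  expect_equal(ssgsea_sample_score(2 * v + 100, s), base)
  # two samples with identical expression get identical scores
  m <- cbind(s1 = v, s2 = v)
  p <- suppressMessages(ssgsea_project(make_expr(m), list(s),
                                       normalize = FALSE, min_coverage = 0))
  expect_equal(p$scores["s1", ], p$scores["s2", ])
})

test_that("ssGSEA rejects degenerate gene sets", {
  v <- c(g1 = 3, g2 = 2, g3 = 1)
  expect_error(ssgsea_sample_score(v, gene_set("s", c("x1", "x2"))),
               "x1")
  expect_error(ssgsea_sample_score(v, gene_set("s", names(v))),
               "every gene")
})

test_that("projection shapes, normalization and coverage gating", {
  panel <- rand_expr(40, 1, seed = 6)
  sets <- list(gene_set("A", c("g001", "g002")),
               gene_set("B", c("g003", "g004", "g005")))
  p1 <- suppressMessages(ssgsea_project(panel, sets, min_coverage = 0.8))
  expect_equal(dim(p1$scores), c(1L, 2L))
  # normalized: global range is exactly 1 on a non-constant table
  panel2 <- rand_expr(40, 6, seed = 8)
  p2 <- suppressMessages(ssgsea_project(panel2, sets))
  expect_equal(max(p2$scores) - min(p2$scores), 1)
  # insufficient coverage: error names the signature and missing genes
  bad <- list(gene_set("mostly_absent", c("g001", "nope1", "nope2")))
  expect_error(suppressMessages(ssgsea_project(panel2, bad)),
               "mostly_absent.*nope1")
})

test_that("projected panel scores track the planted latent state", {
  pair <- make_sig_pair(50)
  sim <- sim_cell_line_panel(n_lines = 40, signatures = pair,
                             n_background = 400, seed = 17)
  sc <- suppressMessages(ssgsea_project(sim$panel, pair))
  r_up <- cor(sc$scores[, "GSC_signature"], sim$truth$state_score)
  r_dn <- cor(sc$scores[, "DGC_signature"], sim$truth$state_score)
  expect_gt(r_up, 0.8)
  expect_lt(r_dn, -0.8)
})

test_that("preranked GSEA running sum matches hand evaluation", {
  rl <- structure(data.frame(gene_id = paste0("g", 1:4),
                             score = c(3, 2, 1, 0.5)),
                  class = c("ranked_list", "data.frame"))
  g <- gsea_preranked(rl, gene_set("s", "g1"), weight = 0,
                      n_perm = 100, seed = 2)
  expect_equal(g$es, 1.0)  # running sum 1, 2/3, 1/3, 0
  expect_lte(abs(g$es), 1)
  expect_gte(g$p_value, 1 / (g$n_perm + 1))
  expect_lte(g$p_value, 1)
})

test_that("preranked GSEA is seed-reproducible and bounded", {
  expr <- rand_expr(200, 6, seed = 31)
  rl <- snr_rank(expr, paste0("s0", 1:3), paste0("s0", 4:6))
  s <- gene_set("s", rl$gene_id[c(5, 40, 80, 150)])
  g1 <- gsea_preranked(rl, s, n_perm = 200, seed = 77)
  g2 <- gsea_preranked(rl, s, n_perm = 200, seed = 77)
  expect_identical(g1, g2)
  expect_lte(abs(g1$es), 1)
  expect_error(gsea_preranked(rl, s, n_perm = 50), ">= 100")
  expect_error(gsea_preranked(rl, gene_set("s", "absent")), "no member")
})

test_that("a planted top-of-list set attains the minimum permutation p", {
  n <- 2000
  scores <- seq(10, 0.01, length.out = n)
  rl <- structure(data.frame(gene_id = sprintf("g%04d", 1:n),
                             score = scores),
                  class = c("ranked_list", "data.frame"))
  s <- gene_set("top20", sprintf("g%04d", 1:20))
  g <- gsea_preranked(rl, s, n_perm = 1000, seed = 5)
  expect_equal(g$p_value, 1 / (g$n_same_sign + 1))
  expect_gt(g$nes, 1)
})
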