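test_that("expression round trip through TSV and GCT preserves content", {
  x <- rand_expr(5, 4, seed = 7)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gct <- withr::local_tempfile(fileext = ".gct")
  write_expression(x, tsv, format = "tsv")
  write_expression(x, gct, format = "gct")
  back_tsv <- read_expression(tsv)
  back_gct <- read_expression(gct)
  expect_equal(back_tsv$values, x$values)
  expect_equal(back_gct$values, x$values)
  expect_identical(rownames(back_gct$values), rownames(x$values))
  # cross-format agreement
  expect_equal(back_gct$values, back_tsv$values)
})

test_that("expression readers reject duplicates and non-numeric cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g1\t3\t4"), f)
  expect_error(read_expression(f), "g1")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\tx", "g2\t3\t4"), f)
  expect_error(read_expression(f), "row 1.*column 's2'")
  # GCT dimension mismatch
  g <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "3\t2", "Name\tDescription\ts1\ts2",
               "g1\tna\t1\t2"), g)
  expect_error(read_expression(g), "dimension mismatch")
})

test_that("expression container enforces its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_s3_class(expression_matrix(m, units = "TPM"), "expression_matrix")
  m2 <- m; m2[1, 1] <- -1
  expect_error(expression_matrix(m2, units = "TPM"), "non-negative")
  expect_silent(expression_matrix(m2, units = "log2"))
  m3 <- m; m3[1, 1] <- NA
  expect_error(expression_matrix(m3, units = "log2"), "finite")
})

test_that("GMT parsing handles well-formed lines, duplicates and edge cases", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S1\tdesc\tg1\tg2", f)
  sets <- read_gmt(f)
  expect_identical(sets$S1$members, c("g1", "g2"))
  expect_identical(sets$S1$description, "desc")
  # duplicate members collapse with warning
  writeLines("S1\tdesc\tg1\tg1", f)
  expect_warning(sets <- read_gmt(f), "duplicate members")
  expect_identical(sets$S1$members, "g1")
  # short line -> error with line number
  writeLines(c("S1\tdesc\tg1", "S2\tonlydesc"), f)
  expect_error(read_gmt(f), "line 2")
  # duplicate set names
  writeLines(c("S1\td\tg1", "S1\td\tg2"), f)
  expect_error(read_gmt(f), "duplicate gene set")
  # empty file -> empty list
  writeLines(character(0), f)
  expect_length(read_gmt(f), 0)
  # round trip
  pair <- make_sig_pair(5)
  write_gmt(pair, f)
  back <- read_gmt(f)
  expect_identical(back[[1]]$members, pair$high_in_a$members)
  expect_identical(back[[2]]$members, pair$high_in_b$members)
})

test_that("drug response tables round trip, flag missing and keep empty rows", {
  auc <- matrix(c(1.2, NA, 3.4, 5.6, 7.8, 9.1), 2, 3,
                dimnames = list(c("d1", "d2"), c("l1", "l2", "l3")))
  x <- drug_response_table(auc)
  expect_equal(x$n_missing, 1L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_drug_response(x, f)
  back <- suppressMessages(read_drug_response(f))
  expect_equal(back$auc, auc)
  # all-blank row: warning, retained
  auc2 <- rbind(auc, d3 = NA_real_)
  expect_warning(y <- drug_response_table(auc2), "d3")
  expect_equal(nrow(y$auc), 3)
  # duplicate drug id
  auc3 <- auc; rownames(auc3) <- c("d1", "d1")
  expect_error(drug_response_table(auc3), "duplicate drug")
})

test_that("reader output is invariant to row permutations after id alignment", {
  x <- rand_expr(6, 3, seed = 11)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f1)
  perm <- c(4, 1, 6, 2, 5, 3)
  xp <- expression_matrix(x$values[perm, ], units = x$units)
  write_expression(xp, f2)
  a <- read_expression(f1)$values
  b <- read_expression(f2)$values
  expect_equal(b[rownames(a), ], a)
})

test_that("combination matrices validate dose grids and round trip", {
  inh <- matrix(c(0, 10, 30, 20, 35, 45, 40, 50, 70), 3, 3)
  cm <- combination_matrix(c(0, 1, 10), c(0, 1, 10), inh,
                           drug_a = "dasatinib", drug_b = "belinostat")
  f <- withr::local_tempfile(fileext = ".csv")
  write_combination(cm, f)
  back <- read_combination(f, drug_a = "dasatinib", drug_b = "belinostat")
  expect_equal(back$inhibition, cm$inhibition)
  expect_error(combination_matrix(c(1, 10), c(0, 1), inh[1:2, 1:2]),
               "must be 0")
  expect_error(combination_matrix(c(0, 10, 5), c(0, 1, 2), inh),
               "ascending")
  inh2 <- inh; inh2[1, 1] <- 3
  expect_error(combination_matrix(c(0, 1, 10), c(0, 1, 10), inh2),
               "vehicle")
  # normalize re-anchors the vehicle cell
  cm2 <- combination_matrix(c(0, 1, 10), c(0, 1, 10), inh2,
                            normalize = TRUE)
  expect_equal(cm2$inhibition[1, 1], 0)
})
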