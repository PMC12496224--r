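make_score_table <- function(scores) {
  structure(list(scores = scores, normalized = FALSE, alpha = 0.25,
                 coverage = NULL), class = "score_table")
}

test_that("perfect anti-correlation yields r = -1, rank 1, and exclusions work", {
  n <- 20
  y <- seq(0, 1, length.out = n)
  lines <- sprintf("l%02d", 1:n)
  st <- make_score_table(matrix(y, n, 1, dimnames = list(lines, "SIG")))
  auc <- rbind(affine = 5 - 2 * y,          # exact affine decreasing
               flat = rep(3, n),            # zero variance
               noise = withr::with_seed(2, rnorm(n)))
  colnames(auc) <- lines
  res <- suppressMessages(
    correlate_drug_signature(st, drug_response_table(auc), min_n = 10))
  aff <- res[res$drug == "affine", ]
  expect_equal(aff$r, -1)
  expect_equal(aff$p_value, 0)
  expect_equal(aff$rank, 1L)
  flat <- res[res$drug == "flat", ]
  expect_true(is.na(flat$r))
  expect_match(flat$excluded_reason, "zero variance")
  expect_identical(rank_candidates(res, "SIG", k = 1), "affine")
})

test_that("screen statistics are invariant to joint cell-line permutation", {
  n <- 30
  withr::with_seed(11, {
    y <- runif(n)
    auc <- matrix(rnorm(5 * n), 5, n,
                  dimnames = list(paste0("d", 1:5), sprintf("l%02d", 1:n)))
  })
  st <- make_score_table(matrix(y, n, 1,
                                dimnames = list(sprintf("l%02d", 1:n), "SIG")))
  r1 <- suppressMessages(correlate_drug_signature(st, drug_response_table(auc)))
  perm <- sample(n)
  st2 <- make_score_table(st$scores[perm, , drop = FALSE])
  auc2 <- auc[, perm]
  r2 <- suppressMessages(correlate_drug_signature(st2, drug_response_table(auc2)))
  expect_equal(r1$r, r2$r)
  expect_equal(r1$rank, r2$rank)
})

test_that("negating scores negates r and reverses the candidate order", {
  n <- 25
  withr::with_seed(13, {
    y <- runif(n)
    auc <- matrix(rnorm(8 * n), 8, n,
                  dimnames = list(paste0("d", 1:8), sprintf("l%02d", 1:n)))
  })
  lines <- sprintf("l%02d", 1:n)
  st <- make_score_table(matrix(y, n, 1, dimnames = list(lines, "SIG")))
  stn <- make_score_table(-st$scores)
  r1 <- suppressMessages(correlate_drug_signature(st, drug_response_table(auc)))
  r2 <- suppressMessages(correlate_drug_signature(stn, drug_response_table(auc)))
  expect_equal(r2$r, -r1$r)
  expect_identical(rank_candidates(r2, "SIG", k = 8),
                   rev(rank_candidates(r1, "SIG", k = 8)))
})

test_that("missing AUC entries are handled pairwise-complete with min_n gating", {
  n <- 15
  y <- seq_len(n) / n
  lines <- sprintf("l%02d", 1:n)
  st <- make_score_table(matrix(y, n, 1, dimnames = list(lines, "SIG")))
  auc <- rbind(ok = 2 - y, sparse = c(1, 2, rep(NA, n - 2)))
  colnames(auc) <- lines
  res <- suppressMessages(correlate_drug_signature(
    st, suppressWarnings(drug_response_table(auc)), min_n = 10))
  expect_equal(res[res$drug == "ok", "n_pairs"], n)
  expect_match(res[res$drug == "sparse", "excluded_reason"], "n_pairs")
  # no shared lines at all
  bad <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x1", "x2")))
  expect_error(
    suppressMessages(correlate_drug_signature(st, drug_response_table(bad))),
    "shared")
})

test_that("rank_candidates honors k edge cases", {
  n <- 12
  y <- seq_len(n) / n
  lines <- sprintf("l%02d", 1:n)
  st <- make_score_table(matrix(y, n, 1, dimnames = list(lines, "SIG")))
  auc <- matrix(withr::with_seed(3, rnorm(3 * n)), 3, n,
                dimnames = list(paste0("d", 1:3), lines))
  res <- suppressMessages(correlate_drug_signature(st, drug_response_table(auc)))
  expect_identical(rank_candidates(res, "SIG", k = 0), character(0))
  expect_warning(all3 <- rank_candidates(res, "SIG", k = 10), "exceeds")
  expect_length(all3, 3)
  expect_error(rank_candidates(res, "OTHER", k = 1), "not present")
})

test_that("q-values dominate p-values and ranks are a permutation", {
  pair <- make_sig_pair(50)
  sim <- sim_cell_line_panel(n_lines = 30, signatures = pair,
                             n_background = 300, seed = 41)
  sc <- suppressMessages(ssgsea_project(sim$panel, pair))
  dr <- sim_drug_response(sim$truth, n_drugs = 40, n_assoc = 3, seed = 42)
  res <- suppressMessages(correlate_drug_signature(sc, dr$auc))
  tested <- !is.na(res$r)
  expect_true(all(res$q_value[tested] >= res$p_value[tested]))
  for (sig in unique(res$signature)) {
    rk <- res$rank[res$signature == sig & tested]
    expect_setequal(rk, seq_along(rk))
  }
})
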