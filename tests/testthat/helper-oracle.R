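# Test-only brute-force oracle for the ssGSEA statistic: a literal,
# quadratic-time transcription of the two ECDF sums, kept independent of
# the package implementation.
brute_ssgsea <- function(values, members, alpha) {
  nm <- names(values)
  n <- length(values)
  ord <- order(-values, nm, method = "radix")
  sorted_ids <- nm[ord]
  abs_rank <- stats::setNames(seq.int(n, 1), sorted_ids)
  in_set <- sorted_ids[toupper(trimws(sorted_ids)) %in%
                         toupper(trimws(members))]
  total_w <- sum(abs_rank[in_set]^alpha)
  score <- 0
  for (i in seq_len(n)) {
    upto <- sorted_ids[seq_len(i)]
    p_in <- sum(abs_rank[intersect(upto, in_set)]^alpha) / total_w
    p_out <- length(setdiff(upto, in_set)) / (n - length(in_set))
    score <- score + p_in - p_out
  }
  score
}

# Small builders shared across test files
make_expr <- function(values, units = "log2", groups = NULL) {
  expression_matrix(values, units = units, groups = groups)
}

make_sig_pair <- function(n = 50, prefix_a = "up", prefix_b = "dn") {
  structure(list(
    high_in_a = gene_set("GSC_signature", sprintf("%s%03d", prefix_a, seq_len(n))),
    high_in_b = gene_set("DGC_signature", sprintf("%s%03d", prefix_b, seq_len(n))),
    n = as.integer(n)), class = "signature_pair")
}

rand_expr <- function(n_genes, n_samples, seed = 1, units = "log2") {
  m <- withr::with_seed(seed,
    matrix(stats::rnorm(n_genes * n_samples, 5, 2), n_genes, n_samples,
           dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("s%02d", seq_len(n_samples)))))
  expression_matrix(m, units = units)
}
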