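#' Single-sample GSEA enrichment score for one sample
#'
#' Rank-weighted ECDF-difference statistic. Genes are ranked by decreasing
#' expression (ties broken by gene id); with absolute ranks \eqn{r_j}
#' (top gene gets \eqn{r = N}), the score is
#' \deqn{\sum_{i=1}^{N} [P_{in}(i) - P_{out}(i)]}
#' where \eqn{P_{in}(i)} is the fraction of total in-set weight
#' \eqn{r_j^\alpha} accumulated by list position \eqn{i} and
#' \eqn{P_{out}(i)} is the ECDF of the non-members. `alpha = 0` gives the
#' unweighted ECDF difference; `alpha = 0.25` is the GenePattern
#' projection default.
#'
#' Gene-set members are matched to the expression names
#' case-insensitively after whitespace stripping.
#'
#' @param values Named numeric vector: one sample's expression, names are
#'   gene ids.
#' @param gene_set A [gene_set].
#' @param alpha Rank-weighting exponent (>= 0).
#' @return A single enrichment value.
#' @examples
#' v <- c(g1 = 9, g2 = 5, g3 = 2, g4 = 1)
#' ssgsea_sample_score(v, gene_set("top", "g1"), alpha = 0.25)  # 2.0
#' @export
ssgsea_sample_score <- function(values, gene_set, alpha = 0.25) {
  stopifnot(inherits(gene_set, "gene_set"))
  if (is.null(names(values)) || !is.numeric(values))
    stop_ds("'values' must be a named numeric vector")
  if (alpha < 0) stop_ds("'alpha' must be >= 0")
  ids <- names(values)
  n <- length(values)
  member <- norm_gene_id(ids) %in% norm_gene_id(gene_set$members)
  m <- sum(member)
  if (m == 0L)
    stop_ds("no member of set '%s' present in the sample; missing: %s",
            gene_set$name, paste(gene_set$members, collapse = ", "))
  if (m == n)
    stop_ds("set '%s' covers every gene; the non-member ECDF is undefined",
            gene_set$name)
  o <- order_desc_ties_by_id(values, ids)
  in_set <- member[o]
  r <- n - seq_len(n) + 1               # absolute rank, top gene = n
  w <- ifelse(in_set, r^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (n - m)
  sum(p_in - p_out)
}

#' Project an expression panel onto signature gene sets (ssGSEA)
#'
#' Computes [ssgsea_sample_score()] for every sample x signature
#' combination. A signature must attain at least `min_coverage` of its
#' members among the panel's gene ids, otherwise the projection stops with
#' the missing genes named. When `normalize = TRUE` all scores are divided
#' by the global range (max - min) across the whole table, the
#' GenePattern projection convention.
#'
#' @param panel An [expression_matrix] (genes x cell lines).
#' @param signatures A [gene_set], a `signature_pair`, or a list of gene
#'   sets.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide by the global score range (default `TRUE`).
#' @param min_coverage Minimum fraction of each signature's members that
#'   must be present in the panel (default 0.8).
#' @return Object of class `score_table`: list with `scores`
#'   (samples x signatures matrix), `normalized`, `alpha` and per-signature
#'   `coverage`.
#' @export
ssgsea_project <- function(panel, signatures, alpha = 0.25,
                           normalize = TRUE, min_coverage = 0.8) {
  stopifnot(inherits(panel, "expression_matrix"))
  if (inherits(signatures, "gene_set")) signatures <- list(signatures)
  if (inherits(signatures, "signature_pair"))
    signatures <- list(signatures$high_in_a, signatures$high_in_b)
  if (!length(signatures)) stop_ds("no signatures given")
  set_names <- vapply(signatures, `[[`, character(1), "name")
  panel_ids <- norm_gene_id(rownames(panel$values))

  coverage <- numeric(length(signatures))
  for (k in seq_along(signatures)) {
    s <- signatures[[k]]
    present <- norm_gene_id(s$members) %in% panel_ids
    coverage[k] <- mean(present)
    if (coverage[k] < min_coverage)
      stop_ds("signature '%s' coverage %.2f < %.2f; missing genes: %s",
              s$name, coverage[k], min_coverage,
              paste(s$members[!present], collapse = ", "))
  }
  names(coverage) <- set_names
  message(sprintf("ssgsea_project: coverage %s",
                  paste(sprintf("%s=%.2f", set_names, coverage),
                        collapse = ", ")))

  scores <- matrix(NA_real_, ncol(panel$values), length(signatures),
                   dimnames = list(colnames(panel$values), set_names))
  for (j in seq_len(ncol(panel$values))) {
    v <- panel$values[, j]
    names(v) <- rownames(panel$values)
    for (k in seq_along(signatures))
      scores[j, k] <- ssgsea_sample_score(v, signatures[[k]], alpha = alpha)
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  structure(list(scores = scores, normalized = normalize, alpha = alpha,
                 coverage = coverage), class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d samples x %d signatures (alpha = %g%s)\n",
              nrow(x$scores), ncol(x$scores), x$alpha,
              if (x$normalized) ", range-normalized" else ""))
  invisible(x)
}

#' Write a score table as TSV
#'
#' @param x A `score_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(x, path) {
  stopifnot(inherits(x, "score_table"))
  tab <- data.frame(sample_id = rownames(x$scores), x$scores,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for a set of
# member positions within a descending-sorted score vector.
es_running <- function(scores_sorted, member_idx, weight) {
  n <- length(scores_sorted)
  m <- length(member_idx)
  hit <- numeric(n)
  w <- abs(scores_sorted[member_idx])^weight
  if (sum(w) == 0) w <- rep(1, m)      # all-zero member scores: equal weights
  hit[member_idx] <- w / sum(w)
  miss <- numeric(n)
  miss[-member_idx] <- 1 / (n - m)
  running <- cumsum(hit - miss)
  running[which.max(abs(running))]
}

#' Preranked GSEA with gene-label permutation significance
#'
#' Classic weighted Kolmogorov-Smirnov running-sum statistic on a ranked
#' gene list: member hits increment by \eqn{|s|^{weight}} normalized over
#' the set, misses decrement by \eqn{1/(N - |S|)}; the enrichment score
#' (ES) is the signed maximum deviation of the running sum. Significance
#' comes from `n_perm` random gene-label sets of size \eqn{|S|}; the
#' normalized ES divides by the mean |ES| of same-sign permutations, and
#' the p-value is \eqn{(1 + k)/(n_{same} + 1)} where \eqn{k} counts
#' same-sign permutations at least as extreme.
#'
#' @param ranked A `ranked_list` (e.g. from [snr_rank()]).
#' @param gene_set A [gene_set].
#' @param weight Hit-weight exponent (default 1, the classic weighted
#'   statistic; 0 gives the unweighted KS form).
#' @param n_perm Number of gene-label permutations (>= 100).
#' @param seed Integer RNG seed; results are reproducible given the seed.
#' @return Object of class `gsea_result`: list with `es`, `nes`,
#'   `p_value`, `n_perm`, `seed`, `n_same_sign`.
#' @export
gsea_preranked <- function(ranked, gene_set, weight = 1,
                           n_perm = 1000, seed = 1) {
  stopifnot(inherits(ranked, "ranked_list"), inherits(gene_set, "gene_set"))
  if (n_perm < 100) stop_ds("'n_perm' must be >= 100")
  s <- ranked$score
  ids <- norm_gene_id(ranked$gene_id)
  member_idx <- which(ids %in% norm_gene_id(gene_set$members))
  n <- length(s); m <- length(member_idx)
  if (m == 0L)
    stop_ds("no member of set '%s' present in the ranking", gene_set$name)
  if (m == n)
    stop_ds("set '%s' covers the whole ranking", gene_set$name)

  es <- es_running(s, member_idx, weight)
  perm_es <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
    es_running(s, sample.int(n, m), weight)
  }, numeric(1)))
  same <- sign(perm_es) == sign(es) & perm_es != 0
  n_same <- sum(same)
  nes <- if (n_same > 0) es / mean(abs(perm_es[same])) else NA_real_
  k <- sum(same & abs(perm_es) >= abs(es))
  p <- (1 + k) / (n_same + 1)
  structure(list(es = es, nes = nes, p_value = p, n_perm = n_perm,
                 seed = seed, n_same_sign = n_same),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES = %.4f, NES = %.3f, p = %.4g (%d perms, seed %d)\n",
              x$es, x$nes, x$p_value, x$n_perm, x$seed))
  invisible(x)
}
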