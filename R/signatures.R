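#' Rank genes by the signal-to-noise ratio between two groups
#'
#' The classic GSEA-style ranking metric for a two-group contrast:
#' \deqn{SNR = (\mu_A - \mu_B) / (\sigma'_A + \sigma'_B)}
#' where each group standard deviation is floored,
#' \eqn{\sigma' = \max(s, f \cdot |\mu|, a)}, the usual "minimum standard
#' deviation" guard against near-constant genes. Both floors can be set to
#' 0 to recover the raw metric.
#'
#' Positive SNR means higher expression in `group_a`. Ties are broken by
#' gene id (lexicographic) so the ranking is deterministic.
#'
#' @param expr An [expression_matrix].
#' @param group_a,group_b Disjoint character vectors of sample ids, each
#'   of size >= 2.
#' @param sd_floor_frac Fractional floor `f` (default 0.2).
#' @param sd_floor_abs Absolute floor `a` (default 0.2).
#' @param label_a,label_b Group labels carried into downstream signature
#'   names.
#' @return Object of class `ranked_list`: a data.frame with columns
#'   `gene_id` and `score`, sorted by decreasing score, with the group
#'   labels as attributes.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
#'             dimnames = list("g1", paste0("s", 1:6)))
#' snr_rank(expression_matrix(m), paste0("s", 1:3), paste0("s", 4:6),
#'          sd_floor_frac = 0, sd_floor_abs = 0)  # score -1.5
#' @export
snr_rank <- function(expr, group_a, group_b,
                     sd_floor_frac = 0.2, sd_floor_abs = 0.2,
                     label_a = "A", label_b = "B") {
  stopifnot(inherits(expr, "expression_matrix"))
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_ds("each group needs at least 2 samples")
  if (length(intersect(group_a, group_b)))
    stop_ds("groups overlap: %s",
            paste(intersect(group_a, group_b), collapse = ", "))
  missing <- setdiff(c(group_a, group_b), colnames(expr$values))
  if (length(missing))
    stop_ds("sample(s) not in matrix: %s", paste(missing, collapse = ", "))
  if (sd_floor_frac < 0 || sd_floor_abs < 0)
    stop_ds("sd floors must be non-negative")

  va <- expr$values[, group_a, drop = FALSE]
  vb <- expr$values[, group_b, drop = FALSE]
  mu_a <- rowMeans(va); mu_b <- rowMeans(vb)
  sd_a <- apply(va, 1L, stats::sd); sd_b <- apply(vb, 1L, stats::sd)
  fl_a <- pmax(sd_a, sd_floor_frac * abs(mu_a), sd_floor_abs)
  fl_b <- pmax(sd_b, sd_floor_frac * abs(mu_b), sd_floor_abs)
  num <- mu_a - mu_b
  den <- fl_a + fl_b
  score <- ifelse(den == 0 & num == 0, 0, num / den)
  bad <- which(!is.finite(score))
  if (length(bad))
    stop_ds("non-finite SNR for gene(s) %s: zero denominator with the sd floors disabled",
            paste(rownames(expr$values)[bad], collapse = ", "))

  gid <- rownames(expr$values)
  o <- order_desc_ties_by_id(score, gid)
  out <- data.frame(gene_id = gid[o], score = score[o],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "group_a") <- label_a
  attr(out, "group_b") <- label_b
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Extract top/bottom signature gene sets from a ranking
#'
#' Takes the first `n` genes (highest SNR: up in group A) and the last `n`
#' genes (most negative SNR: up in group B, reversed so the strongest gene
#' comes first) of a ranked list. The two sets are disjoint by
#' construction; if the ranking holds fewer than `2n` genes both sets are
#' shrunk with a warning.
#'
#' @param ranked A `ranked_list` from [snr_rank()].
#' @param n Signature size (default 50).
#' @param name_a,name_b Names for the two gene sets; default
#'   `<label>_signature` from the ranking's group labels.
#' @return Object of class `signature_pair`: list with [gene_set]s
#'   `high_in_a`, `high_in_b` and the size `n`.
#' @export
derive_signatures <- function(ranked, n = 50,
                              name_a = NULL, name_b = NULL) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop_ds("'n' must be a positive count")
  n <- as.integer(n)
  n_genes <- nrow(ranked)
  if (n_genes < 2L * n) {
    n_eff <- n_genes %/% 2L
    warn_ds("ranking has %d genes < 2n = %d; shrinking signatures to %d",
            n_genes, 2L * n, n_eff)
    n <- n_eff
  }
  if (n < 1L) stop_ds("too few genes to derive signatures")
  la <- attr(ranked, "group_a") %||% "A"
  lb <- attr(ranked, "group_b") %||% "B"
  if (is.null(name_a)) name_a <- paste0(la, "_signature")
  if (is.null(name_b)) name_b <- paste0(lb, "_signature")
  top <- ranked$gene_id[seq_len(n)]
  bottom <- rev(ranked$gene_id[seq.int(n_genes - n + 1L, n_genes)])
  structure(list(
    high_in_a = gene_set(name_a, top,
                         description = sprintf("top %d by SNR (%s > %s)", n, la, lb)),
    high_in_b = gene_set(name_b, bottom,
                         description = sprintf("bottom %d by SNR (%s > %s)", n, lb, la)),
    n = n), class = "signature_pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.signature_pair <- function(x, ...) {
  cat(sprintf("signature_pair (n = %d):\n  %s: %d genes\n  %s: %d genes\n",
              x$n, x$high_in_a$name, length(x$high_in_a$members),
              x$high_in_b$name, length(x$high_in_b$members)))
  invisible(x)
}

#' Write a ranked list as a two-column preranked TSV
#'
#' Emits the `gene <tab> score` format consumed by preranked GSEA tools
#' (no header).
#'
#' @param ranked A `ranked_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_list"))
  utils::write.table(ranked[, c("gene_id", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column preranked TSV into a ranked list
#'
#' @param path Path to a headerless `gene <tab> score` file.
#' @param label_a,label_b Optional group labels to attach.
#' @return A `ranked_list` (re-sorted by decreasing score, ties by id).
#' @export
read_ranked_list <- function(path, label_a = "A", label_b = "B") {
  if (!file.exists(path)) stop_ds("file not found: %s", path)
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("gene_id", "score"),
                           colClasses = c("character", "numeric"))
  if (anyDuplicated(tab$gene_id))
    stop_ds("duplicate gene id(s) in ranked list: %s",
            paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  o <- order_desc_ties_by_id(tab$score, tab$gene_id)
  out <- tab[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_a") <- label_a
  attr(out, "group_b") <- label_b
  class(out) <- c("ranked_list", "data.frame")
  out
}
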