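#' Correlate signature scores with drug-sensitivity AUC
#'
#' For every (drug, signature) pair, computes the Pearson correlation
#' between the signature scores and the drug's AUC values over the cell
#' lines shared by both tables, using pairwise-complete observations.
#' Because a lower AUC means greater sensitivity, a strongly negative
#' correlation nominates the drug as selectively potent against the
#' cell state the signature tracks. Two-sided p-values use the t
#' transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}; q-values are
#' Benjamini-Hochberg (or Bonferroni) adjusted across drugs within each
#' signature.
#'
#' Drugs with fewer than `min_n` complete pairs or zero variance in
#' either vector are excluded (retained in the output with
#' `excluded_reason` set and no statistics).
#'
#' @param scores A `score_table` from [ssgsea_project()]; its samples are
#'   cell lines.
#' @param auc A [drug_response_table].
#' @param min_n Minimum complete pairs per drug (default 10).
#' @param adjust Multiple-testing method, `"BH"` (default) or
#'   `"bonferroni"`.
#' @return Object of class `screen_result`: a data.frame with columns
#'   `signature`, `drug`, `n_pairs`, `r`, `p_value`, `q_value`, `rank`
#'   (1 = most negative r) and `excluded_reason`.
#' @export
correlate_drug_signature <- function(scores, auc, min_n = 10,
                                     adjust = c("BH", "bonferroni")) {
  stopifnot(inherits(scores, "score_table"),
            inherits(auc, "drug_response_table"))
  adjust <- match.arg(adjust)
  lines_s <- trimws(rownames(scores$scores))
  lines_a <- trimws(colnames(auc$auc))
  shared <- intersect(lines_s, lines_a)
  if (length(shared) == 0L)
    stop_ds("no cell lines shared between score table and AUC table")
  sc <- scores$scores[match(shared, lines_s), , drop = FALSE]
  au <- auc$auc[, match(shared, lines_a), drop = FALSE]
  if (all(is.na(au)))
    stop_ds("AUC table has no measurements on the shared cell lines")

  res <- list()
  for (sig in colnames(sc)) {
    y <- sc[, sig]
    drug <- rownames(au)
    n_pairs <- integer(length(drug))
    r <- p <- rep(NA_real_, length(drug))
    reason <- rep(NA_character_, length(drug))
    for (i in seq_along(drug)) {
      x <- au[i, ]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      n_pairs[i] <- n
      if (n < min_n) { reason[i] <- sprintf("n_pairs < %d", min_n); next }
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        reason[i] <- "zero variance"; next
      }
      ri <- stats::cor(x[ok], y[ok])
      r[i] <- ri
      p[i] <- if (abs(ri) >= 1) 0 else {
        tt <- ri * sqrt((n - 2) / (1 - ri^2))
        2 * stats::pt(-abs(tt), df = n - 2)
      }
    }
    tested <- is.na(reason)
    q <- rep(NA_real_, length(drug))
    q[tested] <- stats::p.adjust(p[tested], method = adjust)
    rank <- rep(NA_integer_, length(drug))
    if (any(tested)) {
      o <- order(r[tested], p[tested], drug[tested], method = "radix")
      rank[tested][o] <- seq_len(sum(tested))
    }
    n_excl <- sum(!tested)
    if (n_excl)
      message(sprintf("screen [%s]: %d drug(s) excluded (%s)", sig, n_excl,
                      paste(unique(reason[!tested]), collapse = "; ")))
    res[[sig]] <- data.frame(signature = sig, drug = drug,
                             n_pairs = n_pairs, r = r, p_value = p,
                             q_value = q, rank = rank,
                             excluded_reason = reason,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Top candidate drugs for a signature
#'
#' Returns the `k` drugs with the most negative correlation between the
#' given signature's score and drug AUC (i.e. drugs to which high-scoring
#' cell lines are most sensitive). Excluded drugs are skipped; ties are
#' already resolved in the screen ranking (smaller p, then drug id).
#'
#' @param result A `screen_result` from [correlate_drug_signature()].
#' @param signature_name Which signature to rank on.
#' @param k Number of candidates (the study takes the top 3 per
#'   signature).
#' @return Character vector of drug ids, best candidate first.
#' @export
rank_candidates <- function(result, signature_name, k = 3) {
  stopifnot(inherits(result, "screen_result"))
  sub <- result[result$signature == signature_name & !is.na(result$rank), ,
                drop = FALSE]
  if (nrow(sub) == 0L && !signature_name %in% result$signature)
    stop_ds("signature '%s' not present in screen result", signature_name)
  if (k < 0) stop_ds("'k' must be >= 0")
  if (k == 0) return(character(0))
  if (k > nrow(sub)) {
    warn_ds("k = %d exceeds %d tested drugs; returning all", k, nrow(sub))
    k <- nrow(sub)
  }
  sub <- sub[order(sub$rank), , drop = FALSE]
  sub$drug[seq_len(k)]
}

#' Write a screen result as CSV
#'
#' @param x A `screen_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_result <- function(x, path) {
  stopifnot(inherits(x, "screen_result"))
  utils::write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
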