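#' Per-gene z-score standardization of a TPM matrix
#'
#' Standardizes each gene (row) to mean 0 and sample standard deviation 1
#' across the samples. Zero-variance rows become all-zero and are flagged
#' in the `"constant_genes"` attribute.
#'
#' @param tpm An [expression_matrix] (or bare numeric matrix) with at
#'   least 2 samples.
#' @return Standardized numeric matrix with a `constant_genes` attribute.
#' @export
zscore_by_gene <- function(tpm) {
  v <- if (inherits(tpm, "expression_matrix")) tpm$values else tpm
  if (!is.matrix(v) || !is.numeric(v)) stop_ds("'tpm' must be numeric")
  if (ncol(v) < 2L) stop_ds("z-scores need at least 2 samples")
  mu <- rowMeans(v)
  sd <- apply(v, 1L, stats::sd)
  constant <- sd == 0
  z <- (v - mu) / ifelse(constant, 1, sd)
  z[constant, ] <- 0
  attr(z, "constant_genes") <- rownames(v)[constant]
  z
}

#' Differential expression by the z-score / t-test / fold-change rule
#'
#' Implements a simple treatment-vs-control DE filter for TPM matrices:
#' genes are z-scored across the compared samples, an unpaired t-test is
#' run per gene on the standardized values, p-values are BH-adjusted
#' across genes, and a gene is called differentially expressed when its
#' TPM fold change is > 2 or < 0.5 (strict) and its FDR is < 0.05
#' (strict). The fold change is computed on raw TPM group means with a
#' pseudocount: `fc = (mean_treat + pc) / (mean_ctrl + pc)`.
#'
#' Testing standardized rather than raw values is deliberate (it
#' reproduces the published filter verbatim); set `on = "log2"` to test
#' `log2(TPM + 1)` instead.
#'
#' @param tpm An [expression_matrix] in TPM units (non-negative).
#' @param control_ids,treatment_ids Disjoint sample-id vectors, >= 2 each
#'   (the source analysis used 3 per group).
#' @param pseudocount Added to both group means before the ratio
#'   (default 0.01 TPM).
#' @param scope Standardize across the two compared groups only
#'   (`"pair"`, default) or across all samples in the matrix (`"all"`).
#' @param on Test `"zscore"` (default) or `"log2"` values.
#' @param var_equal Student t (default `TRUE`) or Welch.
#' @return Object of class `deg_table`: data.frame with `gene_id`, `fc`,
#'   `t_stat`, `p_value`, `q_value`, `is_deg`.
#' @export
deg_test <- function(tpm, control_ids, treatment_ids, pseudocount = 0.01,
                     scope = c("pair", "all"), on = c("zscore", "log2"),
                     var_equal = TRUE) {
  stopifnot(inherits(tpm, "expression_matrix"))
  scope <- match.arg(scope); on <- match.arg(on)
  control_ids <- as.character(control_ids)
  treatment_ids <- as.character(treatment_ids)
  if (length(intersect(control_ids, treatment_ids)))
    stop_ds("control and treatment groups overlap")
  if (length(control_ids) < 2L || length(treatment_ids) < 2L)
    stop_ds("each group needs at least 2 samples")
  missing <- setdiff(c(control_ids, treatment_ids), colnames(tpm$values))
  if (length(missing))
    stop_ds("sample(s) not in matrix: %s", paste(missing, collapse = ", "))
  if (pseudocount < 0) stop_ds("'pseudocount' must be >= 0")

  raw <- tpm$values
  used <- if (scope == "pair") c(control_ids, treatment_ids)
          else colnames(raw)
  mat <- switch(on,
    zscore = zscore_by_gene(raw[, used, drop = FALSE]),
    log2 = log2(raw[, used, drop = FALSE] + 1))

  zc <- mat[, control_ids, drop = FALSE]
  zt <- mat[, treatment_ids, drop = FALSE]
  stats_per_gene <- vapply(seq_len(nrow(mat)), function(i) {
    tt <- tryCatch(
      stats::t.test(zt[i, ], zc[i, ], var.equal = var_equal),
      error = function(e) NULL)
    if (is.null(tt)) c(0, 1) else c(unname(tt$statistic), tt$p.value)
  }, numeric(2))

  mean_c <- rowMeans(raw[, control_ids, drop = FALSE])
  mean_t <- rowMeans(raw[, treatment_ids, drop = FALSE])
  fc <- (mean_t + pseudocount) / (mean_c + pseudocount)
  p <- stats_per_gene[2L, ]
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(raw), fc = fc,
                    t_stat = stats_per_gene[1L, ], p_value = p,
                    q_value = q,
                    is_deg = (fc > 2 | fc < 0.5) & q < 0.05,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Write a DEG table as CSV
#'
#' @param x A `deg_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(x, path) {
  stopifnot(inherits(x, "deg_table"))
  utils::write.table(x, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
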