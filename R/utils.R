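# Internal helpers shared across modules.

# Canonical form for gene identifiers: whitespace-stripped, upper-cased.
# Symbol case is inconsistent across expression resources, so all matching
# between matrices and gene sets goes through this.
norm_gene_id <- function(x) toupper(trimws(as.character(x)))

# stop() without the call, with sprintf-style formatting
stop_ds <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_ds <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ds("'%s' must be a single finite number", name)
  invisible(x)
}

# Deterministic ordering of genes: descending score, ties by identifier.
order_desc_ties_by_id <- function(score, id) order(-score, id, method = "radix")
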