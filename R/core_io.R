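#' Construct a validated expression matrix
#'
#' The basic container for genes x samples expression data, used both for
#' matched stem-like/differentiated culture pairs and for cell-line panels.
#'
#' @param values Numeric matrix (genes in rows, samples in columns) with
#'   unique rownames (gene identifiers) and colnames (sample identifiers).
#' @param units Expression units, `"log2"` (log2-transformed, may be
#'   negative) or `"TPM"` (linear, must be non-negative). Recorded as
#'   metadata; the container cannot verify the claim beyond the sign check.
#' @param groups Optional named character vector mapping sample id to group
#'   label (e.g. `c(GSC_1 = "GSC", ...)`).
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `units` and `groups`.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' expression_matrix(m, units = "TPM")
#' @export
expression_matrix <- function(values, units = c("log2", "TPM"), groups = NULL) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stop_ds("'values' must be a numeric matrix")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop_ds("expression matrix needs rownames (genes) and colnames (samples)")
  dup <- gid[duplicated(gid)]
  if (length(dup))
    stop_ds("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- sid[duplicated(sid)]
  if (length(dup))
    stop_ds("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  if (!all(is.finite(values)))
    stop_ds("expression values must all be finite")
  if (units == "TPM" && any(values < 0))
    stop_ds("TPM expression values must be non-negative")
  if (!is.null(groups)) {
    groups <- groups[sid]
    if (anyNA(groups))
      stop_ds("'groups' must name every sample")
  }
  structure(list(values = values, units = units, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  if (!is.null(x$groups))
    cat("groups:", paste(sprintf("%s=%d", names(table(x$groups)),
                                 table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV or GCT 1.2
#'
#' Plain TSV has a header row of sample ids and gene ids in the first
#' column. GCT 1.2 has a `#1.2` version line, a dimensions line, and
#' `Name`/`Description` columns before the samples.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension / leading `#1.2`), `"tsv"` or
#'   `"gct"`.
#' @inheritParams expression_matrix
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct"),
                            units = "log2", groups = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_ds("file not found: %s", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^#1\\.2", first) || grepl("\\.gct$", path,
                                                   ignore.case = TRUE))
      "gct" else "tsv"
  }
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !grepl("^#1\\.2", lines[1L]))
      stop_ds("not a GCT 1.2 file (missing '#1.2' version line): %s", path)
    dims <- as.integer(strsplit(trimws(lines[2L]), "\t| +")[[1L]])
    tab <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                             colClasses = "character")
    if (nrow(tab) != dims[1L] || (ncol(tab) - 2L) != dims[2L])
      stop_ds("GCT dimension mismatch: header says %d x %d, body is %d x %d",
              dims[1L], dims[2L], nrow(tab), ncol(tab) - 2L)
    gid <- tab[[1L]]
    body <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             colClasses = "character")
    gid <- tab[[1L]]
    body <- tab[, -1L, drop = FALSE]
  }
  dup <- gid[duplicated(gid)]
  if (length(dup))
    stop_ds("duplicate gene id(s) in %s: %s", path,
            paste(unique(dup), collapse = ", "))
  vals <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                 dimnames = list(gid, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]) & trimws(body[[j]]) != "" |
                   trimws(body[[j]]) == "")
    if (length(bad))
      stop_ds("non-numeric cell at row %d (gene '%s'), column '%s' in %s",
              bad[1L], gid[bad[1L]], colnames(body)[j], path)
    vals[, j] <- v
  }
  expression_matrix(vals, units = units, groups = groups)
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' @param x An [expression_matrix].
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
    tab <- data.frame(Name = rownames(v), Description = "na",
                      v, check.names = FALSE)
    utils::write.table(tab, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    tab <- data.frame(gene_id = rownames(v), v, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Construct a gene set
#'
#' @param name Set label.
#' @param members Character vector of gene identifiers (unique, length >= 1).
#' @param description Free text.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, members, description = "") {
  members <- as.character(members)
  if (anyDuplicated(members)) {
    warn_ds("gene set '%s': duplicate members collapsed", name)
    members <- unique(members)
  }
  if (length(members) < 1L) stop_ds("gene set '%s' is empty", name)
  structure(list(name = name, description = description, members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One set per line: `name <tab> description <tab> member <tab> member ...`.
#' Duplicate members within a line are collapsed with a warning; duplicate
#' set names are an error.
#'
#' @param path Path to the GMT file.
#' @return Named list of [gene_set] objects (possibly empty).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_ds("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop_ds("GMT line %d has fewer than 3 fields", i)
    sets[[i]] <- gene_set(f[1L], members = f[-(1:2)], description = f[2L])
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop_ds("duplicate gene set name(s): %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set], a `signature_pair`, or a list of gene sets.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (inherits(sets, "signature_pair"))
    sets <- list(sets$high_in_a, sets$high_in_b)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else "na",
            s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a drug response (AUC) table
#'
#' Drugs x cell-lines matrix of dose-response AUC values; lower AUC means
#' more sensitive. Missing entries are `NA` and all downstream statistics
#' are pairwise-complete.
#'
#' @param auc Numeric matrix, drugs in rows (rownames), cell lines in
#'   columns (colnames); `NA` marks missing measurements.
#' @return Object of class `drug_response_table`.
#' @export
drug_response_table <- function(auc) {
  if (!is.matrix(auc) || !is.numeric(auc))
    stop_ds("'auc' must be a numeric matrix")
  if (is.null(rownames(auc)) || is.null(colnames(auc)))
    stop_ds("AUC matrix needs rownames (drugs) and colnames (cell lines)")
  dup <- rownames(auc)[duplicated(rownames(auc))]
  if (length(dup))
    stop_ds("duplicate drug id(s): %s", paste(unique(dup), collapse = ", "))
  dup <- colnames(auc)[duplicated(colnames(auc))]
  if (length(dup))
    stop_ds("duplicate cell line id(s): %s",
            paste(unique(dup), collapse = ", "))
  if (any(!is.finite(auc) & !is.na(auc)))
    stop_ds("present AUC values must be finite")
  all_na <- rownames(auc)[rowSums(!is.na(auc)) == 0L]
  if (length(all_na))
    warn_ds("drug(s) with no AUC measurements retained: %s",
            paste(all_na, collapse = ", "))
  structure(list(auc = auc, n_missing = sum(is.na(auc))),
            class = "drug_response_table")
}

#' @export
print.drug_response_table <- function(x, ...) {
  cat(sprintf("drug_response_table: %d drugs x %d cell lines (%d missing)\n",
              nrow(x$auc), ncol(x$auc), x$n_missing))
  invisible(x)
}

#' Read a drug response table from CSV/TSV
#'
#' Rows are drugs, columns are cell lines, blank cells are missing.
#'
#' @param path Path to the file.
#' @param sep Field separator; `"auto"` picks tab for `.tsv`/`.txt`, comma
#'   otherwise.
#' @return A [drug_response_table].
#' @export
read_drug_response <- function(path, sep = "auto") {
  if (!file.exists(path)) stop_ds("file not found: %s", path)
  if (identical(sep, "auto"))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character")
  ids <- tab[[1L]]
  body <- tab[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    raw <- trimws(body[[j]])
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & nzchar(raw) & !is.na(raw) & raw != "NA")
    if (length(bad))
      stop_ds("non-numeric AUC at row %d (drug '%s'), column '%s'",
              bad[1L], ids[bad[1L]], colnames(body)[j])
    m[, j] <- v
  }
  out <- drug_response_table(m)
  message(sprintf("read_drug_response: %d of %d entries missing",
                  out$n_missing, length(m)))
  out
}

#' Write a drug response table as CSV
#'
#' @param x A [drug_response_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drug_response <- function(x, path) {
  stopifnot(inherits(x, "drug_response_table"))
  tab <- data.frame(drug_id = rownames(x$auc), x$auc, check.names = FALSE)
  utils::write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Construct a dose-grid combination matrix
#'
#' Percent-inhibition measurements on a two-drug dose grid, with
#' monotherapy margins: the first dose on each axis is 0 (vehicle).
#'
#' @param doses_a,doses_b Strictly ascending concentrations (nM) starting
#'   at 0.
#' @param inhibition Numeric matrix of percent inhibition indexed
#'   `[dose_a, dose_b]`.
#' @param drug_a,drug_b Drug names for the two axes.
#' @param normalize If `TRUE`, subtract the vehicle cell
#'   `inhibition[1, 1]` from the whole matrix so the vehicle anchor is
#'   exactly 0.
#' @return Object of class `combination_matrix`.
#' @export
combination_matrix <- function(doses_a, doses_b, inhibition,
                               drug_a = "drug_A", drug_b = "drug_B",
                               normalize = FALSE) {
  doses_a <- as.numeric(doses_a); doses_b <- as.numeric(doses_b)
  if (doses_a[1L] != 0 || doses_b[1L] != 0)
    stop_ds("first dose on each axis must be 0 (vehicle)")
  if (any(diff(doses_a) <= 0) || any(diff(doses_b) <= 0))
    stop_ds("doses must be strictly ascending")
  if (!is.matrix(inhibition) || nrow(inhibition) != length(doses_a) ||
      ncol(inhibition) != length(doses_b))
    stop_ds("inhibition matrix must be %d x %d to match the dose grids",
            length(doses_a), length(doses_b))
  if (!all(is.finite(inhibition)))
    stop_ds("inhibition values must all be finite")
  if (normalize) inhibition <- inhibition - inhibition[1L, 1L]
  if (abs(inhibition[1L, 1L]) > 1e-8)
    stop_ds("vehicle cell inhibition[0, 0] must be 0 (use normalize = TRUE)")
  dimnames(inhibition) <- list(format(doses_a, trim = TRUE),
                               format(doses_b, trim = TRUE))
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 inhibition = inhibition, drug_a = drug_a, drug_b = drug_b),
            class = "combination_matrix")
}

#' @export
print.combination_matrix <- function(x, ...) {
  cat(sprintf("combination_matrix: %s (%d doses) x %s (%d doses), %% inhibition\n",
              x$drug_a, length(x$doses_a), x$drug_b, length(x$doses_b)))
  print(round(x$inhibition, 2))
  invisible(x)
}

#' Read a combination matrix from long-form CSV
#'
#' Expected columns: `dose_a`, `dose_b`, `inhibition`; one row per grid
#' cell. The grid must be complete.
#'
#' @param path Path to the CSV file.
#' @inheritParams combination_matrix
#' @return A [combination_matrix].
#' @export
read_combination <- function(path, drug_a = "drug_A", drug_b = "drug_B",
                             normalize = FALSE) {
  if (!file.exists(path)) stop_ds("file not found: %s", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("dose_a", "dose_b", "inhibition")
  if (!all(need %in% names(tab)))
    stop_ds("combination CSV needs columns: %s", paste(need, collapse = ", "))
  da <- sort(unique(tab$dose_a)); db <- sort(unique(tab$dose_b))
  m <- matrix(NA_real_, length(da), length(db))
  i <- match(tab$dose_a, da); j <- match(tab$dose_b, db)
  m[cbind(i, j)] <- tab$inhibition
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop_ds("incomplete dose grid: no row for dose_a=%g, dose_b=%g",
            da[miss[1L]], db[miss[2L]])
  }
  combination_matrix(da, db, m, drug_a = drug_a, drug_b = drug_b,
                     normalize = normalize)
}

#' Write a combination matrix as long-form CSV
#'
#' @param x A [combination_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_combination <- function(x, path) {
  stopifnot(inherits(x, "combination_matrix"))
  tab <- expand.grid(dose_a = x$doses_a, dose_b = x$doses_b,
                     KEEP.OUT.ATTRS = FALSE)
  tab$inhibition <- as.vector(x$inhibition)
  utils::write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
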