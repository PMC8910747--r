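#' @keywords internal
"_PACKAGE"

## Core containers are deliberately light-weight: a CountMatrix is an integer
## matrix with unique rownames (genes) and colnames (samples); a SampleTable is
## a data.frame keyed by `sample`.  Validators centralize the id discipline so
## every stage can assume it.

#' Validate (and coerce) a gene-by-sample count matrix
#'
#' Counts must be non-negative integers; gene and sample ids must be unique
#' and non-missing.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   rownames and colnames set.
#' @return the validated matrix, storage mode `integer`.
#' @export
as_count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (anyNA(counts)) stop("NA counts not allowed")
  if (any(counts < 0)) stop("negative counts not allowed")
  if (max(abs(counts - round(counts))) > 1e-8) stop("counts must be integral")
  storage.mode(counts) <- "integer"
  counts
}

#' Validate a sample metadata table
#'
#' @param meta data.frame with at least columns `sample`, `diagnosis`,
#'   `batch`; optional `age_death`, `sex`, `braak`.
#' @param counts optional CountMatrix whose samples must match `meta$sample`
#'   exactly (as sets).
#' @return the validated data.frame.
#' @export
as_sample_table <- function(meta, counts = NULL) {
  req <- c("sample", "diagnosis", "batch")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample)) stop("duplicate sample ids in metadata")
  if (!is.null(counts)) {
    if (!setequal(meta$sample, colnames(counts)))
      stop("sample ids in metadata and count matrix differ")
    meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
    rownames(meta) <- NULL
  }
  meta
}

#' Read / write counts as TSV (first column = gene id)
#'
#' @param path file path.
#' @return `read_counts`: validated integer matrix.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_count_matrix(m)
}

#' @rdname read_counts
#' @param counts CountMatrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata CSV
#'
#' Header: `sample,diagnosis,batch,age_death,sex,braak`.
#' @param path file path.
#' @export
read_sample_table <- function(path) {
  as_sample_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_sample_table
#' @param meta SampleTable.
#' @export
write_sample_table <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- small shared numerics ----

#' Z-standardize a vector (zero-variance safe)
#'
#' Returns all zeros when the standard deviation is zero (degenerate input),
#' matching the convention used for RIF and centrality z-scores.
#' @param x numeric vector.
#' @export
z_standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Adjusted Rand index between two partitions
#'
#' Used to score recovery of planted subtype labels against ground truth.
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

## Derive a stage-specific seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
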