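#' Read an expression matrix
#'
#' Reads a probe-set-by-sample table of log2 signal intensities from either a
#' plain tab-delimited file (header row of sample ids, first column probe
#' ids) or a GEO Series Matrix text file, where the same table sits between
#' the `!series_matrix_table_begin` / `!series_matrix_table_end` marker lines
#' and every line starting with `!` is metadata and skipped. Quoted
#' identifiers are unquoted on read.
#'
#' @param path Path to the file.
#' @param format `"tsv"`, `"geo_series_matrix"`, or `"auto"` (GEO layout is
#'   assumed when the file contains the series-matrix table markers).
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames, row and column order as in the file.
#' @export
read_expression_matrix <- function(path,
                                   format = c("auto", "tsv",
                                              "geo_series_matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_geo <- any(grepl("^!series_matrix_table_begin", lines))
  if (format == "auto") format <- if (is_geo) "geo_series_matrix" else "tsv"
  if (format == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
      stop("malformed series matrix: table markers missing or empty table")
    }
    lines <- lines[(begin + 1L):(end - 1L)]
  }
  lines <- lines[!startsWith(lines, "!")]
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty expression table")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(fields[[1L]])
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) stop("empty expression table: no sample columns")
  n_col <- length(header)
  probe_ids <- character(length(fields) - 1L)
  values <- matrix(NA_real_, nrow = length(fields) - 1L,
                   ncol = length(sample_ids))
  for (i in seq_along(fields)[-1L]) {
    row <- unquote(fields[[i]])
    if (length(row) != n_col) {
      stop(sprintf("row %d has %d fields, expected %d", i, length(row), n_col))
    }
    probe_ids[i - 1L] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("non-numeric value '%s' at row %d, column %d (probe '%s', sample '%s')",
                   row[-1L][j], i, j + 1L, row[1L], sample_ids[j]))
    }
    values[i - 1L, ] <- v
  }
  dup <- probe_ids[duplicated(probe_ids)]
  if (length(dup)) {
    stop(sprintf("duplicate probe id(s): %s",
                 paste(unique(dup), collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in header")
  dimnames(values) <- list(probe_ids, sample_ids)
  validate_expression_matrix(values)
}

validate_expression_matrix <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  if (!all(is.finite(x))) stop("expression matrix contains non-finite values")
  x
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()] for the plain tab-delimited dialect.
#'
#' @param matrix Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name for the first (probe id) column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path, id_column = "probe_id") {
  validate_expression_matrix(matrix)
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2-transform a linear-scale matrix
#'
#' Each value is replaced by `log2(max(value, floor))`; the floor keeps
#' non-positive intensities defined. The caller declares the input scale:
#' the transform is not idempotent and must not be applied to already
#' log2-transformed data.
#'
#' @param matrix Numeric matrix of linear-scale intensities.
#' @param floor Positive clamp applied before taking logs.
#' @return Matrix of log2 intensities, same dimnames.
#' @export
log2_transform <- function(matrix, floor = 1) {
  stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0)
  out <- log2(pmax(matrix, floor))
  out
}

#' Per-probe median across samples
#'
#' The median pseudo-sample: for each probe set, the median of its signal
#' intensities across all samples (even sample counts use the mean of the
#' two central order statistics).
#'
#' @param matrix Numeric matrix, probes in rows.
#' @return Named numeric vector, one value per probe.
#' @export
median_profile <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 1L)
  apply(matrix, 1L, stats::median)
}

#' Group-specificity pre-filter
#'
#' Keeps probe sets whose median in group A exceeds the `percentile_b`-th
#' percentile in group B by more than `fold_change` on the linear scale.
#' Data are log2, so the linear ratio is evaluated as a log2 difference:
#' a probe passes when `median_A - percentile_B > log2(fold_change)`
#' (strict). Percentiles use linear interpolation between order statistics.
#'
#' @param matrix Numeric log2 matrix, probes in rows.
#' @param group_a,group_b Disjoint, non-empty character vectors of sample ids.
#' @param fold_change Linear-scale fold-change threshold (default 3).
#' @param percentile_b Percentile of group B to compare against (default 85).
#' @return Character vector of passing probe ids, largest log2 difference
#'   first.
#' @export
group_specific_filter <- function(matrix, group_a, group_b,
                                  fold_change = 3, percentile_b = 85) {
  validate_expression_matrix(matrix)
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L,
            is.numeric(fold_change), fold_change > 0,
            is.numeric(percentile_b), percentile_b >= 0, percentile_b <= 100)
  if (length(intersect(group_a, group_b))) {
    stop("group_a and group_b overlap")
  }
  missing <- setdiff(c(group_a, group_b), colnames(matrix))
  if (length(missing)) {
    stop(sprintf("unknown sample id(s): %s", paste(missing, collapse = ", ")))
  }
  med_a <- apply(matrix[, group_a, drop = FALSE], 1L, stats::median)
  p_b <- apply(matrix[, group_b, drop = FALSE], 1L, stats::quantile,
               probs = percentile_b / 100, names = FALSE, type = 7)
  diff <- med_a - p_b
  keep <- which(diff > log2(fold_change))
  keep <- keep[order(-diff[keep])]  # stable: ties keep input order
  rownames(matrix)[keep]
}
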