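#' Expression table
#'
#' A features x samples matrix of non-negative expression values (TPM or
#' normalized counts), with the unit recorded.
#'
#' @param values numeric matrix with feature ids as rownames and sample
#'   ids as colnames; no negative entries.
#' @param unit character, e.g. "TPM" or "normalized_counts".
#' @return object of class `ExpressionTable`.
#' @export
expression_table <- function(values, unit = "TPM") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have feature rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0, na.rm = TRUE)) stop("negative expression values")
  structure(list(values = values, unit = unit), class = "ExpressionTable")
}

#' @export
print.ExpressionTable <- function(x, ...) {
  cat(sprintf("ExpressionTable: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Filter features by a minimum expression in a minimum number of samples
#'
#' A feature is kept when its value is at least `min_value` (inclusive) in
#' at least `min_samples` samples. The defaults reproduce the standard
#' detection filter of TPM >= 0.1 in >= 2 samples.
#'
#' @param expr an [expression_table()] or a plain numeric matrix.
#' @param min_value minimum expression value, inclusive.
#' @param min_samples minimum number of samples meeting `min_value`.
#' @return character vector of feature ids passing the filter.
#' @export
filter_expressed <- function(expr, min_value = 0.1, min_samples = 2L) {
  v <- if (inherits(expr, "ExpressionTable")) expr$values else as.matrix(expr)
  stop_if_not_scalar_number(min_value, "min_value", min = 0)
  stop_if_not_scalar_number(min_samples, "min_samples", min = 1)
  if (min_samples > ncol(v)) {
    stop("min_samples exceeds the number of samples")
  }
  keep <- rowSums(v >= min_value) >= min_samples
  rownames(v)[keep]
}

#' ATAC-seq peak set
#'
#' Genomic peak intervals with per-sample accessibility counts and an
#' optional per-peak differential-accessibility label.
#'
#' @param peaks data.frame with columns `peak_id`, `chrom`, `start`,
#'   `end` (0-based half-open); strand is unstranded by convention.
#' @param counts numeric peak x sample matrix; rownames must equal the
#'   peak ids.
#' @param da_label optional named logical vector per peak.
#' @return object of class `PeakSet`.
#' @export
peak_set <- function(peaks, counts = NULL, da_label = NULL) {
  needed <- c("peak_id", "chrom", "start", "end")
  if (!all(needed %in% names(peaks))) {
    stop("peaks must have columns: ", paste(needed, collapse = ", "))
  }
  peaks <- as.data.frame(peaks)[, needed]
  if (anyDuplicated(peaks$peak_id)) stop("duplicate peak ids")
  if (any(peaks$end <= peaks$start)) stop("peak with end <= start")
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) ||
        !identical(sort(rownames(counts)), sort(peaks$peak_id))) {
      stop("counts rownames must match peak ids")
    }
    counts <- counts[peaks$peak_id, , drop = FALSE]
    if (any(counts < 0)) stop("negative peak counts")
  }
  if (!is.null(da_label)) {
    da_label <- da_label[peaks$peak_id]
    stopifnot(is.logical(da_label))
  }
  structure(list(peaks = peaks, counts = counts, da_label = da_label),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet: %d peaks%s\n", nrow(x$peaks),
              if (is.null(x$counts)) ""
              else sprintf(", counts over %d samples", ncol(x$counts))))
  invisible(x)
}

#' Read/write a TSV expression or count matrix
#'
#' First column = feature id, remaining columns = samples (header row).
#'
#' @param path file path.
#' @param unit recorded unit for [expression_table()].
#' @return [expression_table()] for the reader.
#' @export
read_expression <- function(path, unit = "TPM") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, row.names = 1L)
  expression_table(as.matrix(df), unit = unit)
}

#' @rdname read_expression
#' @param expr an [expression_table()].
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write BED intervals (BED3/BED6)
#'
#' @param path file path.
#' @return data.frame with columns chrom, start, end and, when present,
#'   name, score, strand.
#' @export
read_bed <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' @rdname read_bed
#' @param bed data.frame with at least chrom, start, end.
#' @export
write_bed <- function(bed, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(bed))
  utils::write.table(bed[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write PSL-like alignment block tables
#'
#' Columns: query_id, q_chrom, q_start, q_end, t_chrom, t_start, t_end,
#' strand ("+" for same-strand, "-" otherwise), score.
#'
#' @param path file path.
#' @return data.frame of alignment blocks.
#' @export
read_blocks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_blocks(df)
  df
}

#' @rdname read_blocks
#' @param blocks data.frame of alignment blocks.
#' @export
write_blocks <- function(blocks, path) {
  validate_blocks(blocks)
  utils::write.table(blocks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_blocks <- function(df) {
  needed <- c("query_id", "q_chrom", "q_start", "q_end", "t_chrom",
              "t_start", "t_end", "strand", "score")
  if (!all(needed %in% names(df))) {
    stop("blocks must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(df) > 0) {
    if (any(df$q_end <= df$q_start) || any(df$t_end <= df$t_start)) {
      stop("block with non-positive length")
    }
    if (any(df$score < 0)) stop("negative block score")
    if (!all(df$strand %in% c("+", "-"))) stop("block strand must be +/-")
  }
  invisible(df)
}
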