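#' Binned Hi-C contact map
#'
#' Symmetric within-chromosome contact counts at a fixed bin size, with a
#' per-bin validity mask. Masked bins carry no information downstream.
#'
#' @param counts symmetric, non-negative square matrix of contact counts.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @param valid_mask logical vector, one entry per bin; `FALSE` marks bins
#'   excluded from all analyses. Defaults to all valid.
#' @return object of class `ContactMap`.
#' @export
contact_map <- function(counts, bin_size, chrom = "chr1", valid_mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts))) {
    stop("counts must be symmetric")
  }
  stop_if_not_scalar_number(bin_size, "bin_size", min = 1)
  n <- nrow(counts)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, n)
  stopifnot(is.logical(valid_mask), length(valid_mask) == n)
  structure(list(chrom = chrom, bin_size = as.integer(bin_size),
                 n_bins = n, counts = unname(counts),
                 valid_mask = valid_mask),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap %s: %d bins x %d bp, %d masked, total %.4g\n",
              x$chrom, x$n_bins, x$bin_size, sum(!x$valid_mask),
              sum(x$counts)))
  invisible(x)
}

#' Read a contact map from a bins BED file plus a bin-pair COO file
#'
#' The bins file is a BED of equal-width bins (last bin may be shorter at
#' the chromosome end) whose 4th column is the 0-based bin index. The
#' pairs file has three columns `bin_i bin_j count` with count > 0;
#' counts are stored symmetrically and absent pairs are zero.
#'
#' @param bins_path path to the bins BED file.
#' @param pairs_path path to the 3-column bin-pair count file.
#' @return a [contact_map()].
#' @export
read_contact_map <- function(bins_path, pairs_path) {
  bins <- utils::read.table(bins_path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "index"),
                            colClasses = c("character", "integer", "integer",
                                           "integer"))
  if (nrow(bins) == 0L) stop("bins file is empty")
  if (length(unique(bins$chrom)) != 1L) {
    stop("bins file must describe a single chromosome")
  }
  bins <- bins[order(bins$index), ]
  widths <- bins$end - bins$start
  n <- nrow(bins)
  if (n > 1L && any(widths[-n] != widths[1L])) {
    stop("unequal bin widths (only the chromosome-end bin may be shorter)")
  }
  if (widths[n] > widths[1L]) stop("chromosome-end bin wider than bin size")
  counts <- matrix(0, n, n)
  info <- file.info(pairs_path)
  if (!is.na(info$size) && info$size > 0) {
    pr <- utils::read.table(pairs_path, sep = "\t", header = FALSE,
                            col.names = c("i", "j", "count"))
    if (nrow(pr) > 0L) {
      if (any(pr$i < 0 | pr$i >= n | pr$j < 0 | pr$j >= n)) {
        stop("bin index out of range in pairs file")
      }
      if (any(pr$count <= 0)) stop("pair counts must be > 0")
      ii <- pr$i + 1L; jj <- pr$j + 1L
      for (k in seq_len(nrow(pr))) {
        counts[ii[k], jj[k]] <- counts[ii[k], jj[k]] + pr$count[k]
        if (ii[k] != jj[k]) {
          counts[jj[k], ii[k]] <- counts[jj[k], ii[k]] + pr$count[k]
        }
      }
    }
  }
  cm <- contact_map(counts, bin_size = widths[1L], chrom = bins$chrom[1L])
  attr(cm, "partial_end_bin") <- widths[n] < widths[1L]
  cm
}

#' Write a contact map as bins BED + bin-pair COO text
#'
#' @param cm a [contact_map()].
#' @param bins_path,pairs_path output paths.
#' @export
write_contact_map <- function(cm, bins_path, pairs_path) {
  n <- cm$n_bins
  bins <- data.frame(chrom = cm$chrom,
                     start = (seq_len(n) - 1L) * cm$bin_size,
                     end = seq_len(n) * cm$bin_size,
                     index = seq_len(n) - 1L)
  utils::write.table(bins, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts > 0,
              arr.ind = TRUE)
  pairs <- data.frame(i = ut[, 1L] - 1L, j = ut[, 2L] - 1L,
                      count = cm$counts[ut])
  pairs <- pairs[order(pairs$i, pairs$j), ]
  utils::write.table(pairs, pairs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(bins_path, pairs_path))
}
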