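#' Promoter accessibility per gene
#'
#' The promoter of a transcript is the 1 kb region strictly upstream of
#' its TSS (mirrored on the minus strand). Every peak overlapping any
#' promoter region of a gene by >= 1 bp contributes its counts to that
#' gene; multiple contributing peaks are summed element-wise. Genes with
#' no promoter peak are absent from the result. A peak overlapping
#' promoters of several genes contributes to each; those peaks are listed
#' in the `ambiguous_peaks` attribute.
#'
#' @param peaks a [peak_set()] with per-sample counts.
#' @param ann an [annotation()].
#' @param upstream_bp promoter length upstream of the TSS.
#' @return gene x sample numeric matrix of summed promoter-peak counts,
#'   with attribute `ambiguous_peaks`.
#' @export
promoter_accessibility <- function(peaks, ann, upstream_bp = 1000L) {
  stopifnot(inherits(peaks, "PeakSet"))
  if (is.null(peaks$counts)) stop("peaks must carry per-sample counts")
  tt <- derive_tss_tts(ann)$by_transcript
  plus <- tt$strand == "+"
  prom_s <- ifelse(plus, tt$tss - upstream_bp, tt$tss + 1L)
  prom_e <- ifelse(plus, tt$tss, tt$tss + 1L + upstream_bp)
  prom_s <- pmax(prom_s, 0L)
  keep <- prom_e > prom_s
  tt <- tt[keep, , drop = FALSE]
  pgr <- GenomicRanges::GRanges(peaks$peaks$chrom,
                                IRanges::IRanges(peaks$peaks$start + 1L,
                                                 peaks$peaks$end))
  rgr <- GenomicRanges::GRanges(tt$chrom,
                                IRanges::IRanges(prom_s[keep] + 1L,
                                                 prom_e[keep]))
  ov <- GenomicRanges::findOverlaps(pgr, rgr)
  if (length(ov) == 0L) {
    return(structure(matrix(numeric(0), 0, ncol(peaks$counts),
                            dimnames = list(NULL, colnames(peaks$counts))),
                     ambiguous_peaks = character(0)))
  }
  pairs <- unique(data.frame(
    peak = peaks$peaks$peak_id[S4Vectors::queryHits(ov)],
    gene = tt$gene_id[S4Vectors::subjectHits(ov)]))
  genes <- sort(unique(pairs$gene))
  out <- matrix(0, length(genes), ncol(peaks$counts),
                dimnames = list(genes, colnames(peaks$counts)))
  for (k in seq_len(nrow(pairs))) {
    out[pairs$gene[k], ] <- out[pairs$gene[k], ] +
      peaks$counts[pairs$peak[k], ]
  }
  npg <- table(pairs$peak)
  structure(out, ambiguous_peaks = names(npg)[npg > 1L])
}

#' Per-gene correlation of expression and promoter accessibility
#'
#' For each gene present in both tables, the Pearson correlation of
#' log10(expression + pseudocount) and log10(accessibility + pseudocount)
#' over the shared samples where both values are available. Genes with
#' fewer than `min_samples` shared samples, or a constant vector, give
#' NA.
#'
#' @param expr an [expression_table()] or gene x sample matrix.
#' @param access gene x sample accessibility matrix (e.g. from
#'   [promoter_accessibility()]).
#' @param log_pseudocount pseudocount added before log10.
#' @param min_samples minimum shared samples to emit a correlation.
#' @return data.frame with gene_id, n (shared samples) and r.
#' @export
expression_accessibility_correlation <- function(expr, access,
                                                 log_pseudocount = 1e-3,
                                                 min_samples = 3L) {
  e <- if (inherits(expr, "ExpressionTable")) expr$values else as.matrix(expr)
  a <- as.matrix(access)
  samples <- intersect(colnames(e), colnames(a))
  if (length(samples) == 0L) stop("no shared samples")
  genes <- intersect(rownames(e), rownames(a))
  le <- log10(e[genes, samples, drop = FALSE] + log_pseudocount)
  la <- log10(a[genes, samples, drop = FALSE] + log_pseudocount)
  r <- vapply(seq_along(genes), function(k) {
    x <- le[k, ]; y <- la[k, ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_samples) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  n <- vapply(seq_along(genes), function(k) {
    sum(!is.na(le[k, ]) & !is.na(la[k, ]))
  }, numeric(1))
  data.frame(gene_id = genes, n = as.integer(n), r = r, row.names = NULL)
}

#' Accessibility distributions per expression quartile
#'
#' Ranks genes by expression within one sample (ties broken by gene id
#' for reproducibility), splits them into four quartiles of near-equal
#' size (sizes differ by at most 1), and groups the accessibility values
#' by quartile.
#'
#' @param expr named numeric vector of per-gene expression in one sample.
#' @param access named numeric vector of per-gene accessibility, same
#'   gene set.
#' @return list with `values` (list of 4 numeric vectors, lowest to
#'   highest expression quartile) and `summary` (data.frame quartile, n,
#'   median).
#' @export
quartile_accessibility <- function(expr, access) {
  if (!setequal(names(expr), names(access))) {
    stop("expr and access must cover the same genes")
  }
  n <- length(expr)
  if (n < 4L) stop("need at least 4 genes")
  access <- access[names(expr)]
  o <- order(expr, names(expr))
  q <- floor((seq_len(n) - 1L) * 4L / n) + 1L
  vals <- split(unname(access[o]), q)
  names(vals) <- paste0("Q", 1:4)
  list(values = vals,
       summary = data.frame(quartile = names(vals),
                            n = lengths(vals),
                            median = vapply(vals, stats::median, numeric(1)),
                            row.names = NULL))
}

#' Hierarchical clustering of samples on orthologous gene expression
#'
#' Pairwise sample similarity is the Pearson correlation of
#' log10(TPM + 1e-3) over the ortholog feature set; the clustering
#' distance is 1 - r^2 with complete-linkage agglomeration. Samples are
#' ordered by id beforehand so the result is deterministic.
#'
#' @param expr an [expression_table()].
#' @param ortholog_features character vector of feature ids to restrict
#'   to (must intersect the table's features).
#' @param k optional number of flat clusters to cut.
#' @return list with `dist` (the 1 - r^2 distance matrix), `hclust`, and
#'   `clusters` (named integer vector when `k` is given).
#' @export
cluster_samples <- function(expr, ortholog_features = NULL, k = NULL) {
  v <- if (inherits(expr, "ExpressionTable")) expr$values else as.matrix(expr)
  if (ncol(v) < 2L) stop("need at least 2 samples")
  if (!is.null(ortholog_features)) {
    feats <- intersect(rownames(v), ortholog_features)
    if (length(feats) == 0L) stop("feature set empty after restriction")
    v <- v[feats, , drop = FALSE]
  }
  v <- v[, order(colnames(v)), drop = FALSE]
  r <- stats::cor(log10(v + 1e-3))
  d <- 1 - r^2
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  list(dist = d, hclust = hc,
       clusters = if (!is.null(k)) stats::cutree(hc, k = k) else NULL)
}

#' Write an hclust tree in Newick format
#'
#' @param hc an `hclust` object (e.g. from [cluster_samples()]).
#' @param path output path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
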