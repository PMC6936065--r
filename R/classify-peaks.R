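#' Genomic-domain classification of peaks
#'
#' Assigns each peak the subset of nine genomic domains it belongs to,
#' relative to a gene annotation (a peak may be in several domains):
#' \itemize{
#' \item exonic: overlaps an annotated exon by >= 1 bp.
#' \item intronic: totally included in an annotated intron.
#' \item tss / tts: the peak contains an annotated TSS / TTS.
#' \item tss1Kb / tts1Kb: overlaps a TSS / TTS extended 1 kb both sides.
#' \item tss5Kb / tts5Kb: same with 5 kb.
#' \item intergenic: does not overlap any gene extended by 5 kb on each
#'   side (exclusive of all other labels).
#' }
#'
#' @param peaks a [peak_set()] or data.frame with peak_id, chrom, start,
#'   end.
#' @param ann an [annotation()].
#' @return logical matrix peaks x 9 domains, rownames = peak ids.
#' @export
classify_peaks <- function(peaks, ann) {
  pk <- if (inherits(peaks, "PeakSet")) peaks$peaks else as.data.frame(peaks)
  doms <- c("exonic", "intronic", "tss", "tss1Kb", "tss5Kb",
            "tts", "tts1Kb", "tts5Kb", "intergenic")
  out <- matrix(FALSE, nrow(pk), length(doms),
                dimnames = list(pk$peak_id, doms))
  if (nrow(pk) == 0L || nrow(ann$exons) == 0L) {
    out[, "intergenic"] <- TRUE
    return(out)
  }
  pgr <- GenomicRanges::GRanges(pk$chrom,
                                IRanges::IRanges(pk$start + 1L, pk$end))
  ex <- ann$exons
  egr <- GenomicRanges::GRanges(ex$chrom,
                                IRanges::IRanges(ex$start + 1L, ex$end))
  out[, "exonic"] <- IRanges::overlapsAny(pgr, egr)

  intr <- do.call(rbind, lapply(transcript_list(ann), function(e) {
    ir <- introns_of(e)
    if (nrow(ir) == 0L) return(NULL)
    data.frame(chrom = e$chrom[1L], start = ir$start, end = ir$end)
  }))
  if (!is.null(intr) && nrow(intr) > 0L) {
    igr <- GenomicRanges::GRanges(intr$chrom,
                                  IRanges::IRanges(intr$start + 1L, intr$end))
    out[, "intronic"] <- IRanges::overlapsAny(pgr, igr, type = "within")
  }

  tt <- derive_tss_tts(ann)$by_transcript
  site_hits <- function(pos, chrom, flank) {
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(pos + 1L - flank,
                                                  pos + 1L + flank))
    IRanges::overlapsAny(pgr, gr)
  }
  out[, "tss"] <- site_hits(tt$tss, tt$chrom, 0L)
  out[, "tss1Kb"] <- site_hits(tt$tss, tt$chrom, 1000L)
  out[, "tss5Kb"] <- site_hits(tt$tss, tt$chrom, 5000L)
  out[, "tts"] <- site_hits(tt$tts, tt$chrom, 0L)
  out[, "tts1Kb"] <- site_hits(tt$tts, tt$chrom, 1000L)
  out[, "tts5Kb"] <- site_hits(tt$tts, tt$chrom, 5000L)

  gs <- gene_spans(ann)
  ggr <- GenomicRanges::GRanges(gs$chrom,
                                IRanges::IRanges(pmax(1L, gs$start + 1L - 5000L),
                                                 gs$end + 5000L))
  out[, "intergenic"] <- !IRanges::overlapsAny(pgr, ggr)
  out
}

#' @rdname classify_peaks
#' @param peak one interval as a list/one-row data.frame with chrom,
#'   start, end.
#' @return `classify_peak` returns the character vector of domain labels.
#' @export
classify_peak <- function(peak, ann) {
  pk <- data.frame(peak_id = "p", chrom = peak$chrom, start = peak$start,
                   end = peak$end)
  m <- classify_peaks(pk, ann)
  colnames(m)[m[1L, ]]
}

#' Peak density profile around TSSs and promoter-proximal fraction
#'
#' For every (deduplicated) TSS, peak occupancy is accumulated over
#' [-flank_bp, +flank_bp], oriented 5' to 3' by gene strand, and averaged
#' over TSSs per `bin_bp` bin. Also reports the fraction of peaks that
#' overlap any TSS +/- 1 kb window.
#'
#' @param peaks a [peak_set()] or data.frame of peak intervals.
#' @param ann an [annotation()].
#' @param flank_bp half-width of the profiled window (multiple of
#'   `bin_bp`).
#' @param bin_bp profile bin width.
#' @return list with `profile` (data.frame: position = bin center offset
#'   from the TSS, coverage = mean peak occupancy in [0,1]) and
#'   `fraction_1kb`.
#' @export
tss_density_profile <- function(peaks, ann, flank_bp = 5000L,
                                bin_bp = 100L) {
  if (flank_bp %% bin_bp != 0) stop("flank_bp must be a multiple of bin_bp")
  pk <- if (inherits(peaks, "PeakSet")) peaks$peaks else as.data.frame(peaks)
  tt <- derive_tss_tts(ann)$by_transcript
  tt <- tt[!duplicated(paste(tt$chrom, tt$strand, tt$tss)), , drop = FALSE]
  nb <- 2L * flank_bp / bin_bp
  prof <- matrix(0, nrow(tt), nb)
  by_chrom <- split(seq_len(nrow(pk)), pk$chrom)
  for (k in seq_len(nrow(tt))) {
    rows <- by_chrom[[tt$chrom[k]]]
    if (is.null(rows)) next
    win_s <- tt$tss[k] - flank_bp
    # per-base occupancy over the window (0/1)
    cov <- rep(FALSE, 2L * flank_bp)
    for (r in rows) {
      a <- max(pk$start[r], win_s); b <- min(pk$end[r], win_s + 2L * flank_bp)
      if (b > a) cov[(a - win_s + 1L):(b - win_s)] <- TRUE
    }
    if (tt$strand[k] == "-") cov <- rev(cov)
    prof[k, ] <- colMeans(matrix(cov, nrow = bin_bp))
  }
  centers <- seq(-flank_bp + bin_bp / 2, flank_bp - bin_bp / 2, by = bin_bp)
  frac <- if (nrow(pk) == 0L) NA_real_ else {
    pgr <- GenomicRanges::GRanges(pk$chrom,
                                  IRanges::IRanges(pk$start + 1L, pk$end))
    wgr <- GenomicRanges::GRanges(tt$chrom,
                                  IRanges::IRanges(tt$tss + 1L - 1000L,
                                                   tt$tss + 1L + 1000L))
    mean(IRanges::overlapsAny(pgr, wgr))
  }
  list(profile = data.frame(position = centers, coverage = colMeans(prof)),
       fraction_1kb = frac)
}
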