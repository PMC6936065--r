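#' Positional classification of a transcript against a reference
#'
#' Compares a query transcript model to all reference transcripts on the
#' same chromosome and strand and returns the best class, with priority
#' known > extension > alternative > novel:
#' \itemize{
#' \item known: exon-intron structure strictly identical to a reference
#'   transcript (exact same exons).
#' \item extension: same intron chain, and an extreme exon extends the
#'   reference outward by >= 1 bp on >= 1 side (no shrinkage on either
#'   side). Mono-exonic: the single query exon contains the reference
#'   exon with >= 1 bp of strict extension on >= 1 side.
#' \item alternative: shares at least one intron (identical donor and
#'   acceptor coordinates) with a reference transcript; only available to
#'   multi-exonic queries.
#' \item novel: none of the above.
#' }
#'
#' @param query a one-transcript exon data.frame (columns chrom, strand,
#'   start, end, sorted by start) or an [annotation()] holding exactly one
#'   transcript.
#' @param reference an [annotation()].
#' @return a single character: "known", "extension", "alternative" or
#'   "novel".
#' @export
classify_transcript <- function(query, reference) {
  if (inherits(query, "Annotation")) {
    if (n_transcripts(query) != 1L) stop("query must hold one transcript")
    query <- query$exons
  }
  query <- query[order(query$start), , drop = FALSE]
  if (nrow(query) == 0L) stop("query has no exons")
  idx <- reference_class_index(reference)
  classify_one(query, idx)
}

#' Positional classification of all transcripts of an annotation
#'
#' Vectorized form of [classify_transcript()].
#'
#' @param queries an [annotation()] of query transcript models.
#' @param reference the reference [annotation()].
#' @return data.frame with transcript_id, gene_id and class.
#' @export
classify_transcripts <- function(queries, reference) {
  idx <- reference_class_index(reference)
  sp <- transcript_list(queries)
  cls <- vapply(sp, function(e) classify_one(e, idx), character(1))
  data.frame(transcript_id = names(sp),
             gene_id = vapply(sp, function(e) e$gene_id[1L], character(1)),
             class = unname(cls), row.names = NULL)
}

# Precomputed lookup structures for the four classification rules.
reference_class_index <- function(reference) {
  stopifnot(inherits(reference, "Annotation"))
  sp <- transcript_list(reference)
  key <- vapply(sp, function(e) paste(e$chrom[1L], e$strand[1L]), character(1))
  exon_sig <- vapply(sp, function(e) paste(e$start, e$end, collapse = ";"),
                     character(1))
  intron_sig <- vapply(sp, function(e) {
    ir <- introns_of(e)
    paste(ir$start, ir$end, collapse = ";")
  }, character(1))
  span <- t(vapply(sp, function(e) c(e$start[1L], e$end[nrow(e)]),
                   numeric(2)))
  mono <- vapply(sp, nrow, integer(1)) == 1L
  introns <- lapply(sp, function(e) {
    ir <- introns_of(e)
    if (nrow(ir) == 0L) character(0) else paste(ir$start, ir$end)
  })
  list(key = key, exon_sig = exon_sig, intron_sig = intron_sig,
       span = span, mono = mono, introns = introns)
}

classify_one <- function(ex, idx) {
  same <- idx$key == paste(ex$chrom[1L], ex$strand[1L])
  if (!any(same)) return("novel")
  q_exon <- paste(ex$start, ex$end, collapse = ";")
  if (any(idx$exon_sig[same] == q_exon)) return("known")
  q_ir <- introns_of(ex)
  q_intron <- paste(q_ir$start, q_ir$end, collapse = ";")
  q_start <- ex$start[1L]; q_end <- ex$end[nrow(ex)]
  mono_q <- nrow(ex) == 1L
  cand <- which(same & idx$intron_sig == q_intron & idx$mono == mono_q)
  for (r in cand) {
    r_start <- idx$span[r, 1L]; r_end <- idx$span[r, 2L]
    contains <- q_start <= r_start && q_end >= r_end
    extends <- q_start < r_start || q_end > r_end
    if (contains && extends) return("extension")
  }
  if (!mono_q) {
    q_set <- paste(q_ir$start, q_ir$end)
    for (r in which(same)) {
      if (length(idx$introns[[r]]) && any(q_set %in% idx$introns[[r]])) {
        return("alternative")
      }
    }
  }
  "novel"
}
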