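#' Gene annotation container
#'
#' An `Annotation` bundles exon-structured transcript models with gene
#' membership and gene biotypes. All coordinates are 0-based, half-open
#' (BED convention); GTF input/output converts at the boundary.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` ("+" or "-"), `start`, `end` (0-based half-open).
#'   One row per exon.
#' @param biotype named character vector mapping `gene_id` to one of
#'   `"protein_coding"`, `"lncRNA"`, `"other"`. Genes absent from the map
#'   are assigned `"other"`.
#' @return An object of class `Annotation` with elements `exons`
#'   (validated, sorted by transcript then start) and `biotype`.
#' @export
annotation <- function(exons, biotype = NULL) {
  needed <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!all(needed %in% names(exons))) {
    stop("exons must have columns: ", paste(needed, collapse = ", "))
  }
  exons <- as.data.frame(exons)[, needed]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) > 0) {
    if (any(exons$start < 0)) stop("exon start < 0")
    if (any(exons$end <= exons$start)) stop("exon with end <= start")
    if (!all(exons$strand %in% c("+", "-"))) {
      stop("transcript strand must be '+' or '-'")
    }
    exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    # per-transcript sanity: one chrom/strand/gene, non-overlapping exons
    sp <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (ix in sp) {
      if (length(unique(exons$chrom[ix])) != 1L ||
          length(unique(exons$strand[ix])) != 1L ||
          length(unique(exons$gene_id[ix])) != 1L) {
        stop("transcript '", exons$transcript_id[ix[1]],
             "' mixes chrom/strand/gene_id")
      }
      if (length(ix) > 1L &&
          any(exons$start[ix][-1L] < exons$end[ix][-length(ix)])) {
        stop("transcript '", exons$transcript_id[ix[1]],
             "' has overlapping exons")
      }
    }
  }
  gids <- unique(exons$gene_id)
  bt <- stats::setNames(rep("other", length(gids)), gids)
  if (!is.null(biotype) && length(biotype)) {
    keep <- intersect(names(biotype), gids)
    bt[keep] <- unname(biotype[keep])
  }
  structure(list(exons = exons, biotype = bt), class = "Annotation")
}

#' @export
print.Annotation <- function(x, ...) {
  cat("Annotation:", length(unique(x$exons$transcript_id)), "transcripts,",
      length(x$biotype), "genes\n")
  invisible(x)
}

#' Number of transcripts in an Annotation
#' @param ann an [annotation()] object.
#' @return integer count.
#' @export
n_transcripts <- function(ann) length(unique(ann$exons$transcript_id))

# split exon table into per-transcript data.frames (sorted by start)
transcript_list <- function(ann) {
  split(ann$exons, ann$exons$transcript_id)
}

# gene spans: union of the gene's transcript spans
gene_spans <- function(ann) {
  ex <- ann$exons
  if (nrow(ex) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  }
  agg_s <- tapply(ex$start, ex$gene_id, min)
  agg_e <- tapply(ex$end, ex$gene_id, max)
  first <- ex[!duplicated(ex$gene_id), c("gene_id", "chrom", "strand")]
  first <- first[match(names(agg_s), first$gene_id), ]
  data.frame(gene_id = names(agg_s), chrom = first$chrom,
             start = as.integer(agg_s), end = as.integer(agg_e),
             strand = first$strand, row.names = NULL)
}

# introns of one transcript given its sorted exon data.frame
introns_of <- function(ex) {
  if (nrow(ex) < 2L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1L])
}

#' Read a GTF file into an Annotation
#'
#' Parses exon features of a GTF 2.2 file (1-based closed coordinates) and
#' converts them to the package's 0-based half-open convention. The
#' `gene_biotype` attribute is used when present.
#'
#' @param path path to a GTF file.
#' @return An [annotation()] object.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(annotation(empty_exon_df()))
  nfield <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nfield < 8L)) {
    bad <- which(keep)[which(nfield < 8L)[1L]]
    stop(sprintf("malformed GTF line %d: fewer than 8 tab-separated fields",
                 bad))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) return(annotation(empty_exon_df()))
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id)) {
    stop("GTF exon features must carry gene_id and transcript_id")
  }
  ex <- data.frame(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr)
  )
  bt <- NULL
  if (!is.null(gr$gene_biotype)) {
    first <- !duplicated(gr$gene_id)
    bt <- stats::setNames(as.character(gr$gene_biotype[first]),
                          gr$gene_id[first])
    bt[is.na(bt)] <- "other"
  }
  annotation(ex, bt)
}

empty_exon_df <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer())
}

#' Write an Annotation to a GTF file
#'
#' Emits one `exon` feature per exon, converting back to GTF's 1-based
#' closed coordinates. `read_gtf(write_gtf(x))` round-trips losslessly.
#'
#' @param ann an [annotation()] object.
#' @param path output path.
#' @export
write_gtf <- function(ann, path) {
  ex <- ann$exons
  if (nrow(ex) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand
  )
  gr$type <- "exon"
  gr$source <- "epicross"
  gr$gene_id <- ex$gene_id
  gr$transcript_id <- ex$transcript_id
  gr$gene_biotype <- unname(ann$biotype[ex$gene_id])
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Derive TSS and TTS positions per gene
#'
#' The transcription start site of a transcript is its 5' end with respect
#' to strand (`start` on "+", `end - 1` on "-"); the termination site is
#' the 3' end. Gene-level position lists are deduplicated.
#'
#' @param ann an [annotation()] object with at least one transcript.
#' @return list with elements `by_transcript` (data.frame transcript_id,
#'   gene_id, chrom, strand, tss, tts) and `tss`, `tts`: named lists of
#'   deduplicated integer positions per gene.
#' @export
derive_tss_tts <- function(ann) {
  ex <- ann$exons
  if (nrow(ex) == 0L) stop("annotation is empty")
  sp <- transcript_list(ann)
  tx <- do.call(rbind, lapply(sp, function(e) {
    data.frame(transcript_id = e$transcript_id[1L], gene_id = e$gene_id[1L],
               chrom = e$chrom[1L], strand = e$strand[1L],
               tss = if (e$strand[1L] == "+") e$start[1L] else e$end[nrow(e)] - 1L,
               tts = if (e$strand[1L] == "+") e$end[nrow(e)] - 1L else e$start[1L])
  }))
  rownames(tx) <- NULL
  list(
    by_transcript = tx,
    tss = lapply(split(tx$tss, tx$gene_id), function(v) sort(unique(v))),
    tts = lapply(split(tx$tts, tx$gene_id), function(v) sort(unique(v)))
  )
}
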