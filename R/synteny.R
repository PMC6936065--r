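#' Detect syntenically conserved lncRNAs across species
#'
#' A lncRNA is syntenically conserved across a set of species when
#' (1) it lies between two orthologous protein-coding genes,
#' (2) it is the only lncRNA in that intergenic gap in every species, and
#' (3) the relative gene order and orientation of the
#' (coding, lncRNA, coding) triplet is identical in all species, up to a
#' simultaneous reversal of order and strands (whole-genome orientation
#' is arbitrary). A lncRNA divergently overlapping a flanking gene (zero
#' distance) is still eligible as long as it reaches into the gap.
#'
#' @param annotations named list of [annotation()] objects, one per
#'   species; biotypes must distinguish "protein_coding" and "lncRNA".
#' @param orthology data.frame of 1-to-1 coding-gene orthologs, one
#'   column per species (names matching `annotations`), one row per
#'   ortholog group.
#' @return data.frame of conserved triplets: ortholog row indices of the
#'   flanks plus, per species, the lncRNA id and flanking gene ids.
#' @export
detect_syntenic_lncrnas <- function(annotations, orthology) {
  species <- names(annotations)
  if (is.null(species) || !all(species %in% names(orthology))) {
    stop("species absent from orthology table")
  }
  cand <- lapply(species, function(sp) {
    syntenic_candidates(annotations[[sp]],
                        stats::setNames(seq_len(nrow(orthology)),
                                        orthology[[sp]]))
  })
  names(cand) <- species
  ref <- cand[[1L]]
  empty <- data.frame(left_row = integer(), right_row = integer())
  if (nrow(ref) == 0L) return(empty)
  keys <- lapply(cand, function(df) paste(df$row_lo, df$row_hi))
  out <- list()
  for (k in seq_len(nrow(ref))) {
    key <- keys[[1L]][k]
    rows <- lapply(seq_along(species), function(si) {
      hit <- which(keys[[si]] == key)
      if (length(hit) == 1L) cand[[si]][hit, , drop = FALSE] else NULL
    })
    if (any(vapply(rows, is.null, logical(1)))) next
    pat <- vapply(rows, function(r) oriented_pattern(r, ref_lo_first = TRUE),
                  character(1))
    if (length(unique(pat)) != 1L) next
    rec <- data.frame(left_row = ref$row_lo[k], right_row = ref$row_hi[k])
    for (si in seq_along(species)) {
      r <- rows[[si]]
      rec[[paste0(species[si], "_lnc")]] <- r$lnc_id
      rec[[paste0(species[si], "_left")]] <- r$left_id
      rec[[paste0(species[si], "_right")]] <- r$right_id
    }
    out[[length(out) + 1L]] <- rec
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$left_row), , drop = FALSE]
  }

# Per-species candidate triplets: consecutive coding-gene pairs whose gap
# holds exactly one lncRNA. `row_of` maps the species' coding gene ids to
# ortholog row indices (genes absent from the orthology cannot anchor a
# conserved triplet and are still used for adjacency).
syntenic_candidates <- function(ann, row_of) {
  gs <- gene_spans(ann)
  gs$biotype <- unname(ann$biotype[gs$gene_id])
  out <- list()
  for (ch in unique(gs$chrom)) {
    g <- gs[gs$chrom == ch, , drop = FALSE]
    coding <- g[g$biotype == "protein_coding", , drop = FALSE]
    coding <- coding[order(coding$start, coding$end), , drop = FALSE]
    lnc <- g[g$biotype == "lncRNA", , drop = FALSE]
    if (nrow(coding) < 2L) next
    for (i in seq_len(nrow(coding) - 1L)) {
      L <- coding[i, ]; R <- coding[i + 1L, ]
      gap_s <- L$end; gap_e <- R$start
      if (gap_e <= gap_s) next
      inside <- lnc$end > gap_s & lnc$start < gap_e
      if (sum(inside) != 1L) next
      x <- lnc[inside, ]
      rl <- row_of[L$gene_id]; rr <- row_of[R$gene_id]
      if (is.na(rl) || is.na(rr)) next
      lo <- min(rl, rr); hi <- max(rl, rr)
      out[[length(out) + 1L]] <- data.frame(
        row_lo = unname(lo), row_hi = unname(hi),
        lo_is_left = unname(rl) == lo,
        left_id = L$gene_id, right_id = R$gene_id, lnc_id = x$gene_id,
        strand_left = L$strand, strand_lnc = x$strand,
        strand_right = R$strand)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(row_lo = integer(), row_hi = integer(),
                      lo_is_left = logical(), left_id = character(),
                      right_id = character(), lnc_id = character(),
                      strand_left = character(), strand_lnc = character(),
                      strand_right = character()))
  }
  do.call(rbind, out)
}

# Canonical strand pattern of a candidate triplet, oriented so that the
# flank with the lower ortholog row comes first; when that requires
# reading the locus right-to-left, order and strands flip together.
oriented_pattern <- function(r, ref_lo_first = TRUE) {
  pat <- c(r$strand_left, r$strand_lnc, r$strand_right)
  if (!r$lo_is_left) {
    flip <- function(s) ifelse(s == "+", "-", "+")
    pat <- rev(flip(pat))
  }
  paste(pat, collapse = "")
}
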