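#' Best hit among the alignment blocks of one query
#'
#' Returns the block with the maximal score; ties are broken by smallest
#' target start, then smallest target chromosome id, so the choice is
#' deterministic.
#'
#' @param blocks data.frame of alignment blocks for one query (see
#'   [read_blocks()] for columns).
#' @return the selected one-row data.frame.
#' @export
select_best_hit <- function(blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) stop("no blocks given")
  o <- order(-blocks$score, blocks$t_start, blocks$t_chrom)
  blocks[o[1L], , drop = FALSE]
}

#' Merge species-tagged best hits into similarity clusters
#'
#' Overlapping-or-abutting target intervals are merged (single linkage,
#' bedtools-merge analog). A cluster receiving more than one hit from the
#' same species is flagged ambiguous and carries no similarity level; for
#' the rest the similarity level is the number of distinct species.
#'
#' @param hits data.frame with columns `species`, `feature_id`, `chrom`,
#'   `start`, `end` (target-genome coordinates of best hits, one row per
#'   source feature).
#' @return data.frame of clusters: chrom, start, end, n_members, species
#'   (comma-separated), members (comma-separated feature ids), ambiguous,
#'   similarity_level (NA for ambiguous clusters).
#' @export
build_similarity_clusters <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_members = integer(),
                      species = character(), members = character(),
                      ambiguous = logical(), similarity_level = integer()))
  }
  gr <- GenomicRanges::GRanges(hits$chrom,
                               IRanges::IRanges(hits$start + 1L, hits$end))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  out <- lapply(seq_along(red), function(k) {
    rows <- revmap[[k]]
    spp <- hits$species[rows]
    amb <- anyDuplicated(spp) > 0L
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(red))[k],
      start = GenomicRanges::start(red)[k] - 1L,
      end = GenomicRanges::end(red)[k],
      n_members = length(rows),
      species = paste(sort(unique(spp)), collapse = ","),
      members = paste(hits$feature_id[rows], collapse = ","),
      ambiguous = amb,
      similarity_level = if (amb) NA_integer_ else length(unique(spp))
    )
  })
  do.call(rbind, out)
}

#' Chain collinear alignment blocks of one query
#'
#' Finds, among same-strand blocks collinear on both query and target,
#' the maximum-total-score chain by dynamic programming (longest path on
#' the strict-ordering DAG; no gap penalty). The chain is accepted only
#' if query coverage >= `min_coverage`, total score >= `min_score` and
#' chained target length >= `min_length`; otherwise NULL is returned.
#' Default thresholds: stranded mode with coverage 0.4, score 3000 and
#' length cutoff 5000, with block score = aligned bases.
#'
#' @param blocks data.frame of alignment blocks sharing one query id.
#' @param query_length query feature length used for the coverage
#'   denominator; defaults to the query span of the blocks.
#' @param min_coverage minimum chained-bases / query-length fraction.
#' @param min_score minimum total chained score.
#' @param min_length minimum chained length on the target (bp, first
#'   block start to last block end).
#' @return NULL, or a list with `blocks` (the chained rows, in chain
#'   order), `total_score`, `query_coverage`, `chained_length`, and
#'   `target_span` (chrom, start, end of the projected feature).
#' @export
chain_blocks <- function(blocks, query_length = NULL, min_coverage = 0.4,
                         min_score = 3000, min_length = 5000) {
  if (nrow(blocks) == 0L) return(NULL)
  if (length(unique(blocks$query_id)) != 1L) {
    stop("blocks must share one query id")
  }
  if (is.null(query_length)) {
    query_length <- max(blocks$q_end) - min(blocks$q_start)
  }
  best <- NULL
  for (st in unique(blocks$strand)) {
    for (tc in unique(blocks$t_chrom[blocks$strand == st])) {
      b <- blocks[blocks$strand == st & blocks$t_chrom == tc, , drop = FALSE]
      ch <- chain_dp(b, same_strand = st == "+")
      if (!is.null(ch) &&
          (is.null(best) || ch$total_score > best$total_score)) {
        best <- ch
      }
    }
  }
  if (is.null(best)) return(NULL)
  cov <- sum(best$blocks$q_end - best$blocks$q_start) / query_length
  tspan <- c(min(best$blocks$t_start), max(best$blocks$t_end))
  clen <- tspan[2L] - tspan[1L]
  if (cov < min_coverage || best$total_score < min_score ||
      clen < min_length) {
    return(NULL)
  }
  list(blocks = best$blocks, total_score = best$total_score,
       query_coverage = cov, chained_length = clen,
       target_span = data.frame(chrom = best$blocks$t_chrom[1L],
                                start = tspan[1L], end = tspan[2L]))
}

# Maximum-score chain among blocks of one strand/target chrom.
# Collinear: strictly increasing (non-overlapping, ordered) on the query;
# on the target, increasing for same-strand, decreasing otherwise.
chain_dp <- function(b, same_strand) {
  n <- nrow(b)
  if (n == 0L) return(NULL)
  o <- order(b$q_start, b$q_end)
  b <- b[o, , drop = FALSE]
  score <- b$score
  prev <- rep(0L, n)
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      q_ok <- b$q_end[i] <= b$q_start[j]
      t_ok <- if (same_strand) b$t_end[i] <= b$t_start[j]
              else b$t_start[i] >= b$t_end[j]
      if (q_ok && t_ok && score[i] + b$score[j] > score[j]) {
        score[j] <- score[i] + b$score[j]
        prev[j] <- i
      }
    }
  }
  jbest <- which.max(score)
  path <- integer(0)
  j <- jbest
  while (j != 0L) {
    path <- c(j, path)
    j <- prev[j]
  }
  list(blocks = b[path, , drop = FALSE], total_score = score[jbest])
}

#' Rank-based score comparison stratified by similarity level
#'
#' Within each similarity level, compares the scores of flagged vs
#' unflagged regions with a two-sided Wilcoxon rank-sum test and reports
#' per-stratum summaries.
#'
#' @param scores numeric vector of per-region scores.
#' @param level integer vector of per-region similarity levels.
#' @param flag logical vector (e.g. differentially accessible or not).
#' @return data.frame with one row per (level, flag) group (n, median,
#'   q1, q3) and a `p_value` column repeated within level (NA when a
#'   group is empty).
#' @export
stratified_score_comparison <- function(scores, level, flag) {
  stopifnot(length(scores) == length(level), length(scores) == length(flag))
  out <- list()
  for (lv in sort(unique(level))) {
    s <- scores[level == lv]
    f <- flag[level == lv]
    p <- if (any(f) && any(!f)) {
      stats::wilcox.test(s[f], s[!f], alternative = "two.sided",
                         exact = FALSE)$p.value
    } else NA_real_
    for (fl in c(TRUE, FALSE)) {
      v <- s[f == fl]
      out[[length(out) + 1L]] <- data.frame(
        level = lv, flagged = fl, n = length(v),
        median = if (length(v)) stats::median(v) else NA_real_,
        q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
        q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
        p_value = p)
    }
  }
  do.call(rbind, out)
}
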