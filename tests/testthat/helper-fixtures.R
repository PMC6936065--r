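# In-code fixtures and independent oracles used across the test files.

# Compact transcript builder: exons as list of c(start, end).
tx_df <- function(transcript_id, gene_id, strand, exons, chrom = "chr1") {
  do.call(rbind, lapply(exons, function(e) {
    data.frame(transcript_id = transcript_id, gene_id = gene_id,
               chrom = chrom, strand = strand, start = e[1], end = e[2])
  }))
}

make_annotation <- function(..., biotype = NULL) {
  annotation(do.call(rbind, list(...)), biotype)
}

# ---- independent four-rule classification oracle (plain loops) ----------
oracle_classify <- function(q, refs) {
  q <- q[order(q$start), , drop = FALSE]
  qn <- nrow(q)
  q_introns <- if (qn > 1) cbind(q$end[-qn], q$start[-1]) else
    matrix(numeric(0), 0, 2)
  hit <- c(known = FALSE, extension = FALSE, alternative = FALSE)
  for (r in refs) {
    r <- r[order(r$start), , drop = FALSE]
    if (r$chrom[1] != q$chrom[1] || r$strand[1] != q$strand[1]) next
    rn <- nrow(r)
    r_introns <- if (rn > 1) cbind(r$end[-rn], r$start[-1]) else
      matrix(numeric(0), 0, 2)
    if (qn == rn && all(q$start == r$start) && all(q$end == r$end)) {
      hit["known"] <- TRUE
    } else if (qn == rn && (qn == 1 || all(q_introns == r_introns)) &&
               q$start[1] <= r$start[1] && q$end[qn] >= r$end[rn] &&
               (q$start[1] < r$start[1] || q$end[qn] > r$end[rn])) {
      hit["extension"] <- TRUE
    }
    if (qn > 1 && nrow(r_introns) > 0) {
      for (i in seq_len(nrow(q_introns))) {
        for (j in seq_len(nrow(r_introns))) {
          if (all(q_introns[i, ] == r_introns[j, ])) {
            hit["alternative"] <- TRUE
          }
        }
      }
    }
  }
  if (hit["known"]) "known" else if (hit["extension"]) "extension"
  else if (hit["alternative"]) "alternative" else "novel"
}

# all k-exon structures over the breakpoint grid (ordered 2k-subsets)
enumerate_structures <- function(grid, n_exons) {
  combs <- utils::combn(grid, 2 * n_exons)
  lapply(seq_len(ncol(combs)), function(j) {
    b <- combs[, j]
    cbind(start = b[seq(1, length(b), 2)], end = b[seq(2, length(b), 2)])
  })
}

# ---- exhaustive-subset chaining oracle ----------------------------------
oracle_chain_score <- function(blocks, query_length, min_coverage,
                               min_score, min_length) {
  n <- nrow(blocks)
  best <- NULL
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    b <- blocks[sel, , drop = FALSE]
    if (length(unique(b$strand)) > 1 || length(unique(b$t_chrom)) > 1) next
    o <- order(b$q_start)
    b <- b[o, , drop = FALSE]
    m <- nrow(b)
    ok <- TRUE
    if (m > 1) {
      for (i in seq_len(m - 1)) {
        if (b$q_end[i] > b$q_start[i + 1]) { ok <- FALSE; break }
        if (b$strand[1] == "+") {
          if (b$t_end[i] > b$t_start[i + 1]) { ok <- FALSE; break }
        } else {
          if (b$t_start[i] < b$t_end[i + 1]) { ok <- FALSE; break }
        }
      }
    }
    if (!ok) next
    sc <- sum(b$score)
    cov <- sum(b$q_end - b$q_start) / query_length
    clen <- max(b$t_end) - min(b$t_start)
    if (cov < min_coverage || sc < min_score || clen < min_length) next
    if (is.null(best) || sc > best) best <- sc
  }
  best   # NULL when no subset passes the thresholds
}

random_block_fixture <- function(n, seed) {
  withr::with_seed(seed, {
    qs <- sort(sample(0:5000, n))
    qe <- qs + sample(50:800, n, replace = TRUE)
    ts <- sample(0:20000, n)
    data.frame(query_id = "q", q_chrom = "c", q_start = qs, q_end = qe,
               t_chrom = sample(c("h1", "h2"), n, replace = TRUE),
               t_start = ts, t_end = ts + (qe - qs),
               strand = sample(c("+", "-"), n, replace = TRUE),
               score = sample(10:500, n, replace = TRUE))
  })
}

# random symmetric count matrix for balancing / correction tests
random_symmetric_counts <- function(n, seed, positive = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n * n, 20) + if (positive) 1 else 0, n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  })
}

make_track <- function(labels, bin_size = 1e4, chrom = "chrS",
                       eigvec = NULL) {
  structure(list(chrom = chrom, bin_size = bin_size, labels = labels,
                 eigvec = eigvec %||% ifelse(is.na(labels), NA_real_,
                                             ifelse(labels == "A", 1, -1))),
            class = "CompartmentTrack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
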