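#' Simulate promoter accessibility coupled to expression
#'
#' Gives every gene of `ann` one promoter peak (inside the 1 kb region
#' upstream of one of its TSSs) and simulates a gene x sample expression
#' table together with peak x sample accessibility counts. A fraction of
#' genes is positively coupled (accessibility rises with expression across
#' samples), a fraction negatively coupled, and the remainder independent.
#' All signals live on the log10 scale with Gaussian noise of sd
#' `noise_sd`; `noise_sd = 0` makes coupled genes perfectly (anti-)
#' correlated.
#'
#' @param ann an [annotation()] with at least one gene.
#' @param n_samples number of samples (>= 3).
#' @param frac_positive,frac_negative fractions of positively/negatively
#'   coupled genes; their sum must be <= 1.
#' @param noise_sd sd of the log10-scale accessibility noise.
#' @param expr_sd sd of the per-sample log10 expression fluctuation that
#'   drives the coupling.
#' @param seed RNG seed.
#' @return list with `peaks` (a [peak_set()] with counts), `expression`
#'   (an [expression_table()]), and `truth` (named character vector per
#'   gene: "positive", "negative" or "independent").
#' @export
simulate_coupled_peaks_expression <- function(ann, n_samples = 10L,
                                              frac_positive = 0.4,
                                              frac_negative = 0.4,
                                              noise_sd = 0.25,
                                              expr_sd = 0.5,
                                              seed = 1L) {
  if (frac_positive + frac_negative > 1) {
    stop("frac_positive + frac_negative must be <= 1")
  }
  if (n_samples < 3L) stop("n_samples must be >= 3")
  tt <- derive_tss_tts(ann)
  tx <- tt$by_transcript
  tx <- tx[!duplicated(tx$gene_id), , drop = FALSE]  # one TSS per gene
  n_genes <- nrow(tx)
  if (n_genes == 0L) stop("annotation has no genes")

  with_seed(seed, {
    n_pos <- round(frac_positive * n_genes)
    n_neg <- round(frac_negative * n_genes)
    lab <- rep("independent", n_genes)
    pick <- sample(n_genes)
    lab[pick[seq_len(n_pos)]] <- "positive"
    if (n_neg > 0) lab[pick[n_pos + seq_len(n_neg)]] <- "negative"
    names(lab) <- tx$gene_id

    samples <- sprintf("s%02d", seq_len(n_samples))
    mu <- stats::rnorm(n_genes, 1, 0.5)
    delta <- matrix(stats::rnorm(n_genes * n_samples, 0, expr_sd),
                    n_genes, n_samples)
    log_expr <- mu + delta
    expr <- 10^log_expr
    dimnames(expr) <- list(tx$gene_id, samples)

    nu <- stats::rnorm(n_genes, 1.5, 0.3)
    slope <- ifelse(lab == "positive", 1, ifelse(lab == "negative", -1, 0))
    indep <- matrix(stats::rnorm(n_genes * n_samples, 0, expr_sd),
                    n_genes, n_samples)
    log_acc <- nu + slope * delta + (slope == 0) * indep +
      matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd),
             n_genes, n_samples)
    acc <- 10^log_acc
    dimnames(acc) <- list(tx$gene_id, samples)

    # one promoter peak per gene, inside [TSS - 1 kb, TSS)
    off <- sample(100:600, n_genes, replace = TRUE)
    len <- sample(200:400, n_genes, replace = TRUE)
    plus <- tx$strand == "+"
    pk_start <- ifelse(plus, tx$tss - off - len, tx$tss + 1L + off)
    pk_start <- pmax(pk_start, 0L)
    pk_end <- pk_start + len
    peaks <- data.frame(peak_id = sprintf("peak_%s", tx$gene_id),
                        chrom = tx$chrom, start = pk_start, end = pk_end)
    counts <- acc
    rownames(counts) <- peaks$peak_id

    list(
      peaks = peak_set(peaks, counts),
      expression = expression_table(expr, unit = "TPM"),
      truth = lab
    )
  })
}

#' Fragment a feature into collinear alignment blocks
#'
#' Emulates the fragmented projection of a query feature onto a target
#' genome: `n_blocks` same-strand blocks that jointly cover a fraction
#' `1 - gap_frac` of the query, order-consistent on query and target, with
#' per-block score equal to the block length (aligned bases).
#'
#' @param feature list or one-row data.frame with `chrom`, `start`, `end`.
#' @param n_blocks number of blocks (>= 1, at most the feature length).
#' @param gap_frac fraction of the query left uncovered, in [0, 1).
#' @param seed RNG seed.
#' @param query_id id recorded for all blocks.
#' @param target_chrom,target_offset placement of the projection.
#' @return data.frame of alignment blocks (see [read_blocks()] columns).
#' @export
fragment_feature <- function(feature, n_blocks, gap_frac = 0.1, seed = 1L,
                             query_id = "q1", target_chrom = "hchr1",
                             target_offset = 1000L) {
  len <- feature$end - feature$start
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  if (gap_frac < 0 || gap_frac >= 1) stop("gap_frac must be in [0, 1)")
  aligned <- round((1 - gap_frac) * len)
  if (n_blocks > aligned) stop("n_blocks exceeds the feature length")

  with_seed(seed, {
    # random composition of the aligned bases into n_blocks positive parts
    cuts <- sort(sample(aligned - 1L, n_blocks - 1L))
    sizes <- diff(c(0L, cuts, aligned))
    gap_total <- len - aligned
    gaps <- rep(0L, max(0L, n_blocks - 1L))
    if (n_blocks > 1L && gap_total > 0L) {
      p <- stats::runif(n_blocks - 1L)
      gaps <- round(gap_total * p / sum(p))
    }
    q_start <- feature$start + cumsum(c(0L, sizes[-n_blocks] + gaps))
    t_gaps <- if (n_blocks > 1L) sample(0:500, n_blocks - 1L, replace = TRUE)
              else integer(0)
    t_start <- target_offset + cumsum(c(0L, sizes[-n_blocks] + t_gaps))
    data.frame(
      query_id = query_id, q_chrom = feature$chrom,
      q_start = as.integer(q_start), q_end = as.integer(q_start + sizes),
      t_chrom = target_chrom, t_start = as.integer(t_start),
      t_end = as.integer(t_start + sizes),
      strand = "+", score = as.integer(sizes)
    )
  })
}
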