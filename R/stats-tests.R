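#' Cross-species conservation of compartment assignments
#'
#' Tests whether orthologous genes keep the same A/B compartment label
#' across species more often than expected under independence. With
#' per-species observed A-frequencies \eqn{p_A^{(s)}}, the expected
#' number of genes labelled A in all species is \eqn{N\prod_s p_A^{(s)}}
#' (same for B), and the expected number with any identical label is the
#' sum of the two. The observed all-A and all-B counts are each compared
#' to their expectation with a 1-df chi-squared goodness-of-fit test
#' (category vs complement); a combined 2-df test over the three
#' categories (all-A, all-B, discordant) is available via `combined`.
#'
#' @param labels matrix or data.frame of "A"/"B" labels, rows = ortholog
#'   genes, columns = species. Rows with any NA are removed first.
#' @param combined also report a combined 2-df chi-squared test.
#' @return object of class `CompartmentConservationResult`: list with
#'   n_genes, p_A/p_B per species, obs_same, obs_same_A, obs_same_B,
#'   expected_same, excess_percent (unrounded) and
#'   excess_percent_rounded, chi2_A, p_A_test, chi2_B, p_B_test, and
#'   optionally chi2_combined/p_combined. Chi-squared entries are NA when
#'   a species frequency is degenerate (0 or 1).
#' @export
compartment_conservation_test <- function(labels, combined = FALSE) {
  m <- as.matrix(labels)
  keep <- rowSums(is.na(m)) == 0L
  m <- m[keep, , drop = FALSE]
  if (!all(m %in% c("A", "B"))) stop("labels must be 'A' or 'B'")
  n <- nrow(m)
  if (n == 0L) stop("no genes with complete labels")
  p_a <- colMeans(m == "A")
  obs_a <- sum(rowSums(m == "A") == ncol(m))
  obs_b <- sum(rowSums(m == "B") == ncol(m))
  res <- conservation_core(n, p_a, obs_same = obs_a + obs_b,
                           obs_same_a = obs_a, obs_same_b = obs_b)
  if (combined) {
    ea <- n * prod(p_a); eb <- n * prod(1 - p_a)
    if (ea > 0 && eb > 0 && ea + eb < n) {
      O <- c(obs_a, obs_b, n - obs_a - obs_b)
      E <- c(ea, eb, n - ea - eb)
      res$chi2_combined <- sum((O - E)^2 / E)
      res$p_combined <- stats::pchisq(res$chi2_combined, df = 2,
                                      lower.tail = FALSE)
    } else {
      res$chi2_combined <- NA_real_
      res$p_combined <- NA_real_
    }
  }
  res
}

#' @rdname compartment_conservation_test
#'
#' @param n_genes number of orthologous genes with labels in all species.
#' @param p_a per-species observed A-label frequencies.
#' @param obs_same observed count of genes with an identical label in all
#'   species.
#' @param obs_same_a,obs_same_b optional all-A / all-B split of
#'   `obs_same` (needed for the chi-squared tests).
#' @export
compartment_conservation_summary <- function(n_genes, p_a, obs_same,
                                             obs_same_a = NA_integer_,
                                             obs_same_b = NA_integer_) {
  conservation_core(n_genes, p_a, obs_same, obs_same_a, obs_same_b)
}

conservation_core <- function(n, p_a, obs_same, obs_same_a, obs_same_b) {
  stopifnot(all(p_a >= 0 & p_a <= 1), n >= 1)
  p_b <- 1 - p_a
  ea <- n * prod(p_a)
  eb <- n * prod(p_b)
  expected_same <- ea + eb
  excess <- 100 * (obs_same / expected_same - 1)
  gof <- function(obs, expected) {
    if (is.na(obs) || expected <= 0 || expected >= n) {
      return(c(NA_real_, NA_real_))
    }
    stat <- (obs - expected)^2 / expected +
      ((n - obs) - (n - expected))^2 / (n - expected)
    c(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  ga <- gof(obs_same_a, ea)
  gb <- gof(obs_same_b, eb)
  structure(list(
    n_genes = n, p_A = p_a, p_B = p_b,
    obs_same = obs_same, obs_same_A = obs_same_a, obs_same_B = obs_same_b,
    expected_same = expected_same, expected_same_A = ea,
    expected_same_B = eb,
    excess_percent = excess,
    excess_percent_rounded = as.integer(round(excess)),
    chi2_A = ga[1L], p_A_test = ga[2L],
    chi2_B = gb[1L], p_B_test = gb[2L]
  ), class = "CompartmentConservationResult")
}

#' @export
print.CompartmentConservationResult <- function(x, ...) {
  cat(sprintf(
    "Compartment conservation: %d genes, %d same-type (expected %.1f, %+d%%)\n",
    x$n_genes, x$obs_same, x$expected_same, x$excess_percent_rounded))
  if (!is.na(x$chi2_A)) {
    cat(sprintf("  all-A: chi2 = %.2f, p = %.3g\n", x$chi2_A, x$p_A_test))
  }
  if (!is.na(x$chi2_B)) {
    cat(sprintf("  all-B: chi2 = %.2f, p = %.3g\n", x$chi2_B, x$p_B_test))
  }
  invisible(x)
}

#' Permutation test for interval-set overlap
#'
#' Observed statistic: the number (and fraction) of `set_b` intervals
#' overlapping any `set_a` interval by >= 1 bp. The null distribution
#' shuffles `set_a`: each interval is placed uniformly at random on its
#' own chromosome, preserving its length (intervals may overlap each
#' other, as in a bedtools-shuffle analog). The empirical p-value uses
#' the add-one rule \eqn{(1 + \#\{perm \ge obs\}) / (n_{perm} + 1)} and
#' is therefore never 0.
#'
#' @param set_a,set_b data.frames with chrom, start, end (0-based
#'   half-open).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list with observed_count, observed_fraction, p_value and
#'   perm_counts.
#' @export
permutation_overlap_test <- function(set_a, set_b, chrom_sizes,
                                     n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 1L)
  if (nrow(set_b) == 0L) stop("set_b is empty")
  miss <- setdiff(unique(c(set_a$chrom, set_b$chrom)), names(chrom_sizes))
  if (length(miss)) stop("chromosomes missing from chrom_sizes: ",
                         paste(miss, collapse = ","))
  if (nrow(set_a) > 0L) {
    la <- set_a$end - set_a$start
    if (any(la > chrom_sizes[set_a$chrom])) {
      stop("interval longer than its chromosome")
    }
  }
  count_b_hit <- function(a_start, a_end, a_chrom) {
    total <- 0L
    for (ch in unique(set_b$chrom)) {
      bb <- set_b$chrom == ch
      aa <- a_chrom == ch
      if (!any(aa)) next
      mg <- merge_intervals(a_start[aa], a_end[aa])
      total <- total + sum(overlaps_merged(set_b$start[bb], set_b$end[bb],
                                           mg$start, mg$end))
    }
    total
  }
  observed <- if (nrow(set_a) == 0L) 0L else
    count_b_hit(set_a$start, set_a$end, set_a$chrom)
  perm_counts <- with_seed(seed, {
    if (nrow(set_a) == 0L) {
      rep(0L, n_perm)
    } else {
      la <- set_a$end - set_a$start
      room <- chrom_sizes[set_a$chrom] - la
      vapply(seq_len(n_perm), function(p) {
        s <- floor(stats::runif(length(la), 0, room + 1))
        count_b_hit(s, s + la, set_a$chrom)
      }, numeric(1))
    }
  })
  list(observed_count = observed,
       observed_fraction = observed / nrow(set_b),
       p_value = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
       perm_counts = perm_counts)
}
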