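#' Simulate a Hi-C contact map with planted compartments and TADs
#'
#' Expected counts follow a power-law distance decay modulated by planted
#' A/B compartments and TADs:
#' \deqn{\lambda_{ij} \propto (1+|i-j|)^{-\alpha}\,(1 + c\,[comp_i = comp_j])
#'       \,(1 + t\,[same TAD])}
#' with the main diagonal additionally multiplied by `1 + a_diagonal_boost`
#' for A bins (this makes the diagonal-based A/B sign rule identifiable).
#' Counts are drawn as independent Poisson variables on the upper triangle
#' (expected total over unique bin pairs = `depth`) and mirrored.
#'
#' Defaults define the package's reference simulation: a 2 Mb chromosome of
#' 200 x 10 kb bins, alternating 40-bin A/B blocks and 20-bin TADs.
#'
#' @param n_bins number of bins.
#' @param bin_size bin width in bp.
#' @param compartment_profile character vector of per-bin "A"/"B" truth;
#'   default alternates 40-bin blocks starting with A.
#' @param tads data.frame with columns `start_bin`, `end_bin` (0-based,
#'   half-open bin indices) of non-overlapping planted TADs; default tiles
#'   the chromosome with 20-bin TADs.
#' @param depth expected total read-pair count over unique bin pairs.
#' @param decay_exponent power-law distance decay exponent (alpha).
#' @param compartment_boost boost `c` for same-compartment pairs.
#' @param tad_boost boost `t` for same-TAD pairs.
#' @param a_diagonal_boost boost `a` on A-bin diagonal entries.
#' @param seed RNG seed; same parameters and seed give identical output.
#' @param chrom chromosome name.
#' @return list with `map` (a [contact_map()]) and `truth` (list with
#'   `labels`, `tads`, `boundaries_bin`: interior TAD boundary bin indices).
#' @export
simulate_contact_map <- function(n_bins = 200L, bin_size = 10000L,
                                 compartment_profile = NULL, tads = NULL,
                                 depth = 1e6, decay_exponent = 1,
                                 compartment_boost = 1, tad_boost = 0.5,
                                 a_diagonal_boost = 0.5, seed = 1L,
                                 chrom = "chrS") {
  stop_if_not_scalar_number(depth, "depth", min = 0)
  stop_if_not_scalar_number(compartment_boost, "compartment_boost", min = 0)
  stop_if_not_scalar_number(tad_boost, "tad_boost", min = 0)
  stop_if_not_scalar_number(a_diagonal_boost, "a_diagonal_boost", min = 0)
  n <- as.integer(n_bins)
  if (is.null(compartment_profile)) {
    compartment_profile <- rep(rep(c("A", "B"), length.out = ceiling(n / 40)),
                               each = 40L)[seq_len(n)]
  }
  stopifnot(length(compartment_profile) == n,
            all(compartment_profile %in% c("A", "B")))
  if (is.null(tads)) {
    starts <- seq(0L, n - 1L, by = 20L)
    tads <- data.frame(start_bin = starts, end_bin = pmin(starts + 20L, n))
  }
  tads <- tads[order(tads$start_bin), , drop = FALSE]
  if (nrow(tads) > 1L &&
      any(tads$start_bin[-1L] < tads$end_bin[-nrow(tads)])) {
    stop("planted TADs must be non-overlapping")
  }

  idx <- seq_len(n)
  dmat <- abs(outer(idx, idx, "-"))
  lambda <- (1 + dmat)^(-decay_exponent)
  same_comp <- outer(compartment_profile, compartment_profile, "==")
  lambda <- lambda * (1 + compartment_boost * same_comp)
  tad_id <- rep(NA_integer_, n)
  for (k in seq_len(nrow(tads))) {
    tad_id[(tads$start_bin[k] + 1L):tads$end_bin[k]] <- k
  }
  same_tad <- outer(tad_id, tad_id, function(a, b) !is.na(a) & !is.na(b) & a == b)
  lambda <- lambda * (1 + tad_boost * same_tad)
  diag_boost <- ifelse(compartment_profile == "A", 1 + a_diagonal_boost, 1)
  diag(lambda) <- diag(lambda) * diag_boost

  up <- upper.tri(lambda, diag = TRUE)
  lambda <- lambda * (depth / sum(lambda[up]))

  counts <- matrix(0, n, n)
  counts[up] <- with_seed(seed, stats::rpois(sum(up), lambda[up]))
  counts <- counts + t(counts * upper.tri(counts))

  boundaries <- sort(unique(c(tads$start_bin, tads$end_bin)))
  boundaries <- boundaries[boundaries > 0L & boundaries < n]
  list(
    map = contact_map(counts, bin_size = bin_size, chrom = chrom),
    truth = list(labels = compartment_profile, tads = tads,
                 boundaries_bin = boundaries),
    expected = lambda
  )
}
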