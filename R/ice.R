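#' ICE matrix balancing (iterative proportional fitting)
#'
#' Masks the `low_count_frac` fraction of bins with the lowest marginal
#' sums (plus all zero-sum bins) and iteratively divides the matrix by the
#' outer product of its normalized marginals until the bias update is
#' below `eps` in relative max-norm or `max_iter` is reached. At
#' convergence all unmasked row sums are equal; the total unmasked count
#' is preserved.
#'
#' Defaults mirror a standard Hi-C processing configuration
#' (`max_iter = 100`, `eps = 0.1`, low-count filter 2\%).
#'
#' @param cm a [contact_map()].
#' @param max_iter maximum number of iterations.
#' @param eps convergence threshold on the relative bias change.
#' @param low_count_frac fraction of lowest-marginal bins to mask.
#' @return a balanced [contact_map()] whose `valid_mask` marks the bins
#'   used; masked rows/columns are zero. Attribute `iterations` records
#'   the number of sweeps run.
#' @export
ice_normalize <- function(cm, max_iter = 100L, eps = 0.1,
                          low_count_frac = 0.02) {
  stopifnot(inherits(cm, "ContactMap"))
  m <- cm$counts
  marg <- rowSums(m)
  mask <- cm$valid_mask & marg > 0
  if (low_count_frac > 0 && any(mask)) {
    thr <- stats::quantile(marg[mask], probs = low_count_frac, type = 1)
    low <- mask & marg <= thr
    # mask the lowest fraction, but never everything
    if (sum(mask) - sum(low) >= 2L) mask <- mask & !low
  }
  if (sum(mask) < 2L) stop("fewer than 2 unmasked bins")
  sub <- m[mask, mask, drop = FALSE]
  total <- sum(sub)
  if (total == 0) stop("all unmasked bins are empty")
  iters <- 0L
  for (it in seq_len(max_iter)) {
    s <- rowSums(sub)
    s <- s / mean(s)
    sub <- sub / outer(s, s)
    iters <- it
    if (max(abs(s - 1)) < eps) break
  }
  sub <- sub * (total / sum(sub))
  out <- matrix(0, cm$n_bins, cm$n_bins)
  out[mask, mask] <- sub
  res <- contact_map(out, bin_size = cm$bin_size, chrom = cm$chrom,
                     valid_mask = mask)
  attr(res, "iterations") <- iters
  res
}

#' Distance-effect correction of a balanced contact map
#'
#' Standardizes each cell against the bins at the same genomic distance:
#' \deqn{\hat K_{ij} = (K_{ij} - \bar K^d) / \sigma^d} where \eqn{\bar
#' K^d} and \eqn{\sigma^d} are the mean and standard deviation of the
#' counts over all unmasked bin pairs at distance \eqn{d = |i-j|}. When a
#' distance stratum has fewer than 2 pairs or zero standard deviation the
#' corrected value is set to 0 (keeping bins informative without
#' injecting noise). Masked bins are NA.
#'
#' @param cm a (typically balanced) [contact_map()].
#' @return numeric matrix of distance-corrected values.
#' @export
distance_correct <- function(cm) {
  stopifnot(inherits(cm, "ContactMap"))
  n <- cm$n_bins
  m <- cm$counts
  mask <- cm$valid_mask
  out <- matrix(NA_real_, n, n)
  for (d in 0:(n - 1L)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- mask[i] & mask[j]
    if (!any(ok)) next
    iv <- i[ok]; jv <- j[ok]
    vals <- m[cbind(iv, jv)]
    if (length(vals) >= 2L) {
      s <- stats::sd(vals)
      z <- if (s > 0) (vals - mean(vals)) / s else rep(0, length(vals))
    } else {
      z <- rep(0, length(vals))
    }
    out[cbind(iv, jv)] <- z
    out[cbind(jv, iv)] <- z
  }
  out
}
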