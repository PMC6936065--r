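#' Directionality index of each bin
#'
#' The DI quantifies the upstream vs downstream contact bias of a bin.
#' With A the sum of counts to bins within `window_bp` upstream, B the
#' downstream sum and E = (A+B)/2:
#' \deqn{DI = sign(B-A)\left(\frac{(A-E)^2}{E} + \frac{(B-E)^2}{E}\right)}
#' DI is 0 when A = B or E = 0. Bins within one window of a chromosome
#' edge are flagged.
#'
#' @param cm a [contact_map()].
#' @param window_bp window size in bp (>= 2 bins).
#' @return data.frame with bin (1-based), A, B, E, DI, edge (logical).
#' @export
directionality_index <- function(cm, window_bp = 2e6) {
  stopifnot(inherits(cm, "ContactMap"))
  if (window_bp < 2 * cm$bin_size) stop("window_bp must be >= 2 bins")
  n <- cm$n_bins
  w <- floor(window_bp / cm$bin_size)
  m <- cm$counts
  A <- B <- numeric(n)
  for (i in seq_len(n)) {
    up <- seq.int(max(1L, i - w), i - 1L)
    dn <- seq.int(i + 1L, min(n, i + w))
    A[i] <- if (i > 1L) sum(m[i, up]) else 0
    B[i] <- if (i < n) sum(m[i, dn]) else 0
  }
  E <- (A + B) / 2
  DI <- ifelse(A == B | E == 0, 0,
               sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E))
  data.frame(bin = seq_len(n), A = A, B = B, E = E, DI = DI,
             edge = seq_len(n) <= w | seq_len(n) > n - w)
}

#' Insulation-score profile along a chromosome
#'
#' Within a sliding window the insulation score ratio is the proportion
#' of contacts that span the middle of the window, among all contacts
#' with both ends inside the window (self-pairs i = j included in the
#' denominator). The score is reported at the window midpoint; low values
#' mark strong insulation (TAD boundaries). Windows truncated by the
#' chromosome ends are not reported.
#'
#' @param cm a [contact_map()].
#' @param window_bp sliding-window size, a multiple of 2 bins.
#' @param step_bp step between window midpoints, a multiple of the bin
#'   size.
#' @param use_balanced if TRUE, balance the map with [ice_normalize()]
#'   first; the default follows the valid-pairs (raw count) convention.
#' @return object of class `InsulationProfile`: list with `chrom`,
#'   `positions` (bp midpoints), `scores` (in [0,1] or NA), `window_bp`,
#'   `step_bp`.
#' @export
insulation_profile <- function(cm, window_bp = 5e5, step_bp = 1e4,
                               use_balanced = FALSE) {
  stopifnot(inherits(cm, "ContactMap"))
  bs <- cm$bin_size
  if (step_bp %% bs != 0) stop("step_bp must be a multiple of bin_size")
  if (window_bp %% (2 * bs) != 0) {
    stop("window_bp must be a multiple of 2*bin_size")
  }
  n <- cm$n_bins
  chrom_len <- n * bs
  if (window_bp > chrom_len) stop("window larger than chromosome")
  if (use_balanced) cm <- ice_normalize(cm)
  m <- cm$counts
  mask <- cm$valid_mask
  hw_bins <- window_bp / (2 * bs)
  mids <- seq(window_bp / 2, chrom_len - window_bp / 2, by = step_bp)
  scores <- vapply(mids, function(mp) {
    mid_bin <- mp / bs                       # bins 1..mid_bin end <= mp
    left <- seq.int(mid_bin - hw_bins + 1L, mid_bin)
    right <- seq.int(mid_bin + 1L, mid_bin + hw_bins)
    left <- left[mask[left]]
    right <- right[mask[right]]
    wb <- c(left, right)
    if (length(wb) == 0L) return(NA_real_)
    sub <- m[wb, wb, drop = FALSE]
    denom <- (sum(sub) + sum(diag(sub))) / 2   # unordered pairs, i<=j
    if (denom == 0) return(NA_real_)
    cross <- sum(m[left, right, drop = FALSE])
    cross / denom
  }, numeric(1))
  structure(list(chrom = cm$chrom, positions = mids, scores = scores,
                 window_bp = window_bp, step_bp = step_bp),
            class = "InsulationProfile")
}

#' @export
print.InsulationProfile <- function(x, ...) {
  cat(sprintf("InsulationProfile %s: %d positions, window %g bp, step %g bp\n",
              x$chrom, length(x$positions), x$window_bp, x$step_bp))
  invisible(x)
}

#' Assign each TAD boundary the insulation score of its nearest midpoint
#'
#' @param domains data.frame of TAD intervals with columns `start`, `end`
#'   (bp); boundaries are the unique domain edges.
#' @param profile an [insulation_profile()].
#' @return data.frame with boundary (bp position) and score (NA, with a
#'   warning, for boundaries outside the profiled range).
#' @export
boundary_scores <- function(domains, profile) {
  b <- sort(unique(c(domains$start, domains$end)))
  pos <- profile$positions
  lo <- min(pos) - profile$step_bp / 2
  hi <- max(pos) + profile$step_bp / 2
  sc <- vapply(b, function(x) {
    if (x < lo || x > hi) return(NA_real_)
    d <- abs(pos - x)
    profile$scores[which(d == min(d))[1L]]   # tie -> lower coordinate
  }, numeric(1))
  if (anyNA(sc) && any(b < lo | b > hi)) {
    warning("some boundaries fall outside the profiled range")
  }
  data.frame(boundary = b, score = sc)
}

#' Local minima of an insulation profile
#'
#' Positions whose score is strictly less than or equal to both neighbours
#' and strictly less than at least one (plateau interior points are not
#' repeated). NA scores break the neighbourhood.
#'
#' @param profile an [insulation_profile()].
#' @return integer vector of positions (bp) of the local minima.
#' @export
insulation_minima <- function(profile) {
  s <- profile$scores
  n <- length(s)
  if (n < 3L) return(numeric(0))
  out <- logical(n)
  for (i in 2:(n - 1L)) {
    if (anyNA(s[(i - 1L):(i + 1L)])) next
    out[i] <- s[i] <= s[i - 1L] && s[i] <= s[i + 1L] &&
      (s[i] < s[i - 1L] || s[i] < s[i + 1L])
  }
  profile$positions[out]
}
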