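#' Call A/B compartments from a contact map
#'
#' Runs the full compartment pipeline on one chromosome: ICE balancing,
#' distance correction, bin-by-bin Pearson correlation matrix over the
#' unmasked bins, and the first eigenvector of that correlation matrix.
#' Bins are split by eigenvector sign; the sign group whose bins have the
#' larger mean main-diagonal value in the balanced matrix is labelled A
#' (active chromatin interacts more locally), the other B. Masked bins
#' and bins with a degenerate (constant) corrected profile are NA.
#'
#' @param cm a [contact_map()] with at least 3 unmasked bins.
#' @param max_iter,eps,low_count_frac passed to [ice_normalize()].
#' @return object of class `CompartmentTrack`: list with `chrom`,
#'   `bin_size`, `labels` ("A"/"B"/NA per bin) and `eigvec` (first-PC
#'   value per bin, NA where unlabelled).
#' @export
call_compartments <- function(cm, max_iter = 100L, eps = 0.1,
                              low_count_frac = 0.02) {
  stopifnot(inherits(cm, "ContactMap"))
  if (sum(cm$valid_mask) < 3L) stop("need at least 3 unmasked bins")
  bal <- ice_normalize(cm, max_iter = max_iter, eps = eps,
                       low_count_frac = low_count_frac)
  mask <- bal$valid_mask
  if (sum(mask) < 3L) stop("need at least 3 unmasked bins after filtering")
  z <- distance_correct(bal)
  zs <- z[mask, mask, drop = FALSE]
  ok <- apply(zs, 2L, stats::sd) > 0
  labels <- rep(NA_character_, cm$n_bins)
  eig <- rep(NA_real_, cm$n_bins)
  if (sum(ok) < 3L) stop("all bins degenerate: no informative correlation")
  cc <- stats::cor(zs[ok, ok, drop = FALSE])
  ev <- eigen(cc, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  bins_ok <- which(mask)[ok]
  eig[bins_ok] <- v
  sgn <- sign(v)
  diag_bal <- diag(bal$counts)[bins_ok]
  mean_pos <- if (any(sgn > 0)) mean(diag_bal[sgn > 0]) else -Inf
  mean_neg <- if (any(sgn < 0)) mean(diag_bal[sgn < 0]) else -Inf
  a_sign <- if (mean_pos >= mean_neg) 1 else -1
  labels[bins_ok] <- ifelse(sgn == 0, NA_character_,
                            ifelse(sgn == a_sign, "A", "B"))
  structure(list(chrom = cm$chrom, bin_size = cm$bin_size,
                 labels = labels, eigvec = eig),
            class = "CompartmentTrack")
}

#' @export
print.CompartmentTrack <- function(x, ...) {
  cat(sprintf("CompartmentTrack %s: %d bins (%d A, %d B, %d NA)\n",
              x$chrom, length(x$labels), sum(x$labels == "A", na.rm = TRUE),
              sum(x$labels == "B", na.rm = TRUE), sum(is.na(x$labels))))
  invisible(x)
}

#' Segment a compartment track into labelled intervals
#'
#' Maximal runs of consecutive identical labels become one compartment;
#' NA bins terminate runs and belong to no compartment.
#'
#' @param track a `CompartmentTrack` from [call_compartments()].
#' @return data.frame with chrom, start, end (bp), label, n_bins.
#' @export
segment_compartments <- function(track) {
  lab <- track$labels
  n <- length(lab)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), label = character(),
                      n_bins = integer()))
  }
  key <- ifelse(is.na(lab), "<NA>", lab)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "<NA>"
  data.frame(chrom = track$chrom,
             start = (starts[keep] - 1L) * track$bin_size,
             end = ends[keep] * track$bin_size,
             label = r$values[keep],
             n_bins = r$lengths[keep],
             row.names = NULL)
}

#' Proportion of bins with consistent compartment labels across replicates
#'
#' Among bins informative (non-NA) in at least two replicates, the
#' proportion whose non-NA labels all agree.
#'
#' @param tracks list of `CompartmentTrack`s on the same chromosome and
#'   bin size (>= 2).
#' @return a single proportion in [0, 1] (NaN when no bin qualifies).
#' @export
replicate_consistency <- function(tracks) {
  if (length(tracks) < 2L) stop("need at least 2 replicate tracks")
  bs <- vapply(tracks, function(t) t$bin_size, numeric(1))
  ch <- vapply(tracks, function(t) t$chrom, character(1))
  nb <- vapply(tracks, function(t) length(t$labels), numeric(1))
  if (length(unique(bs)) != 1L || length(unique(ch)) != 1L ||
      length(unique(nb)) != 1L) {
    stop("replicate tracks must share chrom, bin_size and bin count")
  }
  labs <- do.call(cbind, lapply(tracks, function(t) t$labels))
  informative <- rowSums(!is.na(labs)) >= 2L
  agree <- apply(labs, 1L, function(r) {
    r <- r[!is.na(r)]
    length(unique(r)) == 1L
  })
  sum(informative & agree) / sum(informative)
}

#' Write compartment segments as BED (name = label, score = mean eigvec)
#'
#' @param track a `CompartmentTrack`.
#' @param path output path.
#' @export
write_compartments_bed <- function(track, path) {
  seg <- segment_compartments(track)
  if (nrow(seg) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  sc <- vapply(seq_len(nrow(seg)), function(k) {
    b <- (seg$start[k] / track$bin_size + 1L):(seg$end[k] / track$bin_size)
    mean(track$eigvec[b], na.rm = TRUE)
  }, numeric(1))
  write_bed(data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                       name = seg$label, score = signif(sc, 6),
                       strand = "."), path)
  invisible(path)
}
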