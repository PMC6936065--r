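# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure in (params, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop(sprintf("'%s' must be a single finite number >= %s", name, min),
         call. = FALSE)
  }
  invisible(x)
}

# Merge possibly-overlapping intervals on one sequence into disjoint sorted
# intervals (book-ended intervals are merged). Pure vector ops: this sits in
# the permutation-test inner loop.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  s <- start[o]; e <- end[o]
  cm <- cummax(e)
  brk <- c(TRUE, s[-1L] > cm[-length(cm)])
  grp <- cumsum(brk)
  list(start = s[brk], end = unname(tapply(cm, grp, max)))
}

# For query intervals [qs, qe) and *merged, sorted* subject intervals
# [ms, me), return logical: does each query overlap any subject by >= 1 bp?
overlaps_merged <- function(qs, qe, ms, me) {
  if (length(ms) == 0L || length(qs) == 0L) return(rep(FALSE, length(qs)))
  # candidate subject: last one starting at or before the query end - 1
  idx <- findInterval(qe - 1L, ms)
  hit <- idx >= 1L
  hit[hit] <- me[idx[hit]] > qs[hit]
  hit
}
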