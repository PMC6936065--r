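#' Simulate multi-species annotations with planted syntenic lncRNA triplets
#'
#' Lays out the same ordered set of protein-coding genes on one chromosome
#' per species (1-to-1 orthologs, conserved order and strand, species-
#' specific coordinates) and places lncRNAs in the intergenic gaps.
#' `n_planted_triplets` lncRNAs are planted so that they satisfy all three
#' syntenic-conservation criteria (flanked by orthologous coding genes,
#' sole lncRNA in the gap in every species, conserved order/orientation);
#' one planted lncRNA divergently overlaps its upstream flanking gene (the
#' zero-distance case). The remaining lncRNAs are decoys, each violating
#' one criterion: a second lncRNA in the same gap, a lncRNA present in one
#' species only, or a lncRNA whose strand is flipped in the second species.
#'
#' @param n_species number of species (>= 1; strand-flip decoys need >= 2).
#' @param n_coding_genes protein-coding genes per species.
#' @param n_lnc total lncRNAs per the first species.
#' @param n_planted_triplets number of conserved triplets to plant
#'   (`<= n_lnc`).
#' @param chrom_length chromosome length in bp.
#' @param seed RNG seed.
#' @return list with `annotations` (named list of [annotation()], species
#'   "sp1"...), `orthology` (data.frame, one column per species, one row
#'   per coding-gene ortholog group), and `planted` (data.frame of planted
#'   triplets: flank ortholog rows plus per-species lncRNA ids).
#' @export
simulate_multispecies_annotation <- function(n_species = 3L,
                                             n_coding_genes = 20L,
                                             n_lnc = 10L,
                                             n_planted_triplets = 5L,
                                             chrom_length = 2e6,
                                             seed = 1L) {
  n_species <- as.integer(n_species)
  n_coding <- as.integer(n_coding_genes)
  n_lnc <- as.integer(n_lnc)
  n_planted <- as.integer(n_planted_triplets)
  if (n_planted > n_lnc) stop("n_planted_triplets must be <= n_lnc")
  unit <- floor(chrom_length / n_coding)
  if (unit < 5000) stop("chrom_length too small to place genes")

  # decoy events, each occupying one intergenic gap
  decoy_types <- character(0)
  budget <- n_lnc - n_planted
  cycle <- c("pair", "missing", "flip")
  k <- 0L
  while (budget > 0L) {
    ty <- cycle[(k %% 3L) + 1L]
    if (ty == "pair" && budget < 2L) ty <- "missing"
    if (ty == "flip" && n_species < 2L) ty <- "missing"
    decoy_types <- c(decoy_types, ty)
    budget <- budget - if (ty == "pair") 2L else 1L
    k <- k + 1L
  }
  n_gaps_needed <- n_planted + length(decoy_types)
  if (n_gaps_needed > n_coding - 1L) {
    stop("not enough intergenic gaps for the requested lncRNAs")
  }

  species <- sprintf("sp%d", seq_len(n_species))
  with_seed(seed, {
    coding_strand <- sample(c("+", "-"), n_coding, replace = TRUE)
    gap_slots <- sample(n_coding - 1L, n_gaps_needed)
    planted_gaps <- utils::head(gap_slots, n_planted)
    decoy_gaps <- utils::tail(gap_slots, length(decoy_types))
    lnc_strand <- sample(c("+", "-"), n_gaps_needed, replace = TRUE)
    names(lnc_strand) <- as.character(gap_slots)

    out_ann <- list()
    lnc_ids <- matrix(NA_character_, nrow = n_planted, ncol = n_species)
    for (si in seq_len(n_species)) {
      sp <- species[si]
      gene_len <- round(unit * 0.4 * stats::runif(n_coding, 0.9, 1.1))
      gstart <- (seq_len(n_coding) - 1L) * unit +
        round(stats::runif(n_coding, 0, unit * 0.05))
      gend <- gstart + gene_len
      exr <- list()
      bio <- character(0)
      for (g in seq_len(n_coding)) {
        gid <- sprintf("%s_g%03d", sp, g)
        tid <- paste0(gid, ".t1")
        # two exons with a central intron
        e1e <- gstart[g] + round(gene_len[g] * 0.4)
        e2s <- gstart[g] + round(gene_len[g] * 0.6)
        exr[[length(exr) + 1L]] <- data.frame(
          transcript_id = tid, gene_id = gid, chrom = "chr1",
          strand = coding_strand[g],
          start = c(gstart[g], e2s), end = c(e1e, gend[g]))
        bio[gid] <- "protein_coding"
      }
      lcount <- 0L
      add_lnc <- function(gap, strand, u, len_frac, overlap_left = FALSE) {
        lcount <<- lcount + 1L
        gid <- sprintf("%s_lnc%02d", sp, lcount)
        a <- gend[gap]; b <- gstart[gap + 1L]
        gapw <- b - a
        len <- max(200L, round(gapw * len_frac))
        s <- if (overlap_left) a - min(500L, round(gene_len[gap] / 4)) else
          a + round(gapw * u)
        e <- min(s + len, b)
        if (e <= s) e <- s + 50L  # degenerate tiny gap; keep a valid interval
        exr[[length(exr) + 1L]] <<- data.frame(
          transcript_id = paste0(gid, ".t1"), gene_id = gid, chrom = "chr1",
          strand = strand, start = s, end = e)
        bio[gid] <<- "lncRNA"
        gid
      }
      for (p in seq_len(n_planted)) {
        gap <- planted_gaps[p]
        lnc_ids[p, si] <- add_lnc(gap, lnc_strand[as.character(gap)],
                                  u = 0.3, len_frac = 0.2,
                                  overlap_left = (p == 1L))
      }
      for (d in seq_along(decoy_types)) {
        gap <- decoy_gaps[d]
        st <- lnc_strand[as.character(gap)]
        ty <- decoy_types[d]
        if (ty == "pair") {
          add_lnc(gap, st, u = 0.1, len_frac = 0.15)
          add_lnc(gap, st, u = 0.6, len_frac = 0.15)
        } else if (ty == "missing") {
          if (si == 1L) add_lnc(gap, st, u = 0.3, len_frac = 0.2)
        } else { # flip: strand reversed in species 2
          add_lnc(gap, if (si == 2L) setdiff(c("+", "-"), st) else st,
                  u = 0.3, len_frac = 0.2)
        }
      }
      out_ann[[sp]] <- annotation(do.call(rbind, exr), bio)
    }

    orthology <- as.data.frame(
      stats::setNames(lapply(species, function(sp) {
        sprintf("%s_g%03d", sp, seq_len(n_coding))
      }), species)
    )
    planted <- if (n_planted > 0L) {
      df <- data.frame(triplet = seq_len(n_planted),
                       left_row = planted_gaps,
                       right_row = planted_gaps + 1L)
      for (si in seq_len(n_species)) df[[species[si]]] <- lnc_ids[, si]
      df[order(df$left_row), , drop = FALSE]
    } else {
      data.frame(triplet = integer(), left_row = integer(),
                 right_row = integer())
    }
    list(annotations = out_ann, orthology = orthology, planted = planted)
  })
}
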