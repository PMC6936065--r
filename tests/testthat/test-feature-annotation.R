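ref_suite <- function() {
  make_annotation(
    tx_df("r1", "g1", "+", list(c(100, 200), c(300, 400), c(500, 600))),
    tx_df("r2", "g2", "+", list(c(700, 800))),
    tx_df("r3", "g3", "-", list(c(100, 200), c(300, 400))))
}

test_that("transcript classes follow the four positional rules", {
  ref <- ref_suite()
  # strictly identical -> known
  expect_equal(classify_transcript(
    tx_df("q", "g", "+", list(c(100, 200), c(300, 400), c(500, 600))), ref),
    "known")
  # same intron chain, first exon 10 bp further 5' -> extension
  expect_equal(classify_transcript(
    tx_df("q", "g", "+", list(c(90, 200), c(300, 400), c(500, 600))), ref),
    "extension")
  # mono-exonic containment with one side equal -> extension
  expect_equal(classify_transcript(
    tx_df("q", "g", "+", list(c(650, 800))), ref), "extension")
  # shares one intron but different terminal exon -> alternative
  expect_equal(classify_transcript(
    tx_df("q", "g", "+", list(c(100, 200), c(300, 450))), ref),
    "alternative")
  # mono-exonic overlap without containment -> novel (class needs introns)
  expect_equal(classify_transcript(
    tx_df("q", "g", "+", list(c(750, 900))), ref), "novel")
  # minus strand with no shared intron chain or intron -> novel
  expect_equal(classify_transcript(
    tx_df("q", "g", "-", list(c(100, 210), c(320, 400), c(500, 600))), ref),
    "novel")
  # r1's structure on the minus strand still shares r3's intron (200,300)
  expect_equal(classify_transcript(
    tx_df("q", "g", "-", list(c(100, 200), c(300, 400), c(500, 600))), ref),
    "alternative")
  # strand-matched two-exon copy of r3 -> known
  expect_equal(classify_transcript(
    tx_df("q", "g", "-", list(c(100, 200), c(300, 400))), ref), "known")
})

test_that("classifier equals the rule oracle on enumerated structures", {
  ref <- ref_suite()
  refs <- split(ref$exons, ref$exons$transcript_id)
  grid <- seq(0, 1000, by = 100)
  cases <- c(enumerate_structures(grid, 1), enumerate_structures(grid, 2))
  exr <- list(); expected <- character(0); k <- 0
  for (st in c("+", "-")) {
    for (ex in cases) {
      k <- k + 1
      q <- data.frame(transcript_id = sprintf("q%04d", k), gene_id = "gq",
                      chrom = "chr1", strand = st,
                      start = ex[, "start"], end = ex[, "end"])
      exr[[k]] <- q
      expected[sprintf("q%04d", k)] <- oracle_classify(q, refs)
    }
  }
  got <- classify_transcripts(annotation(do.call(rbind, exr)), ref)
  expect_equal(stats::setNames(got$class, got$transcript_id),
               expected[got$transcript_id])
  expect_true(all(c("known", "extension", "alternative", "novel")
                  %in% got$class))
})

test_that("peak domain labels match their definitions and invariants", {
  ann <- make_annotation(
    tx_df("t1", "g1", "+", list(c(10000, 10500), c(20000, 20500))))
  # 10 kb from any gene extended by 5 kb -> intergenic only
  labs <- classify_peak(list(chrom = "chr1", start = 40000, end = 40200), ann)
  expect_equal(labs, "intergenic")
  # contains the TSS inside the first exon
  labs <- classify_peak(list(chrom = "chr1", start = 9900, end = 10100), ann)
  expect_setequal(labs, c("exonic", "tss", "tss1Kb", "tss5Kb"))
  # fully inside the intron, > 5 kb from TSS and TTS
  labs <- classify_peak(list(chrom = "chr1", start = 15100, end = 15300), ann)
  expect_equal(labs, "intronic")

  # invariants on random peaks: intergenic exclusive; tss => tss1Kb => tss5Kb
  pk <- withr::with_seed(3, data.frame(
    peak_id = paste0("p", 1:200), chrom = "chr1",
    start = sample(0:30000, 200)))
  pk$end <- pk$start + 150
  m <- classify_peaks(pk, ann)
  expect_true(all(!m[m[, "intergenic"], colnames(m) != "intergenic"]))
  expect_true(all(m[m[, "tss"], "tss1Kb"]) && all(m[m[, "tss1Kb"], "tss5Kb"]))
  expect_true(all(m[m[, "tts"], "tts1Kb"]) && all(m[m[, "tts1Kb"], "tts5Kb"]))
  expect_true(all(rowSums(m) > 0))
})

test_that("TSS density profile measures promoter-proximal peaks", {
  ann <- make_annotation(
    tx_df("t1", "g1", "+", list(c(50000, 51000))),
    tx_df("t2", "g2", "-", list(c(80000, 81000))))
  # peaks centered on each TSS
  pk <- data.frame(peak_id = c("p1", "p2"), chrom = "chr1",
                   start = c(49900, 80800), end = c(50100, 81100))
  out <- tss_density_profile(pk, ann, flank_bp = 2000, bin_bp = 100)
  expect_equal(out$fraction_1kb, 1)
  mid <- which(abs(out$profile$position) == min(abs(out$profile$position)))
  expect_equal(max(out$profile$coverage), max(out$profile$coverage[mid]))
  # no peaks anywhere near a TSS
  far <- data.frame(peak_id = "p1", chrom = "chr1", start = 1000, end = 1200)
  out2 <- tss_density_profile(far, ann, flank_bp = 2000, bin_bp = 100)
  expect_equal(out2$fraction_1kb, 0)
  expect_true(all(out2$profile$coverage == 0))
})

test_that("promoter accessibility sums contributing peaks per gene", {
  ann <- make_annotation(
    tx_df("t1", "g1", "+", list(c(10000, 12000))),
    tx_df("t2", "g2", "-", list(c(30000, 32000))))
  cnt <- rbind(p1 = c(4, 7), p2 = c(1, 2), p3 = c(10, 20), far = c(5, 5))
  colnames(cnt) <- c("s1", "s2")
  pk <- peak_set(data.frame(
    peak_id = c("p1", "p2", "p3", "far"), chrom = "chr1",
    start = c(9500, 9100, 32100, 50000),
    end = c(9900, 9400, 32500, 50500)), cnt)
  acc <- promoter_accessibility(pk, ann)
  # g1 gets p1 + p2 (both in [TSS-1kb, TSS)); g2 gets p3 (minus strand)
  expect_equal(acc["g1", ], c(s1 = 5, s2 = 9))
  expect_equal(acc["g2", ], c(s1 = 10, s2 = 20))
  expect_false("far" %in% rownames(acc))

  # overlap-scan oracle on the generated coupling fixture
  ms <- simulate_multispecies_annotation(n_species = 1, seed = 12)
  ann2 <- ms$annotations[[1]]
  cp <- simulate_coupled_peaks_expression(ann2, seed = 3)
  acc2 <- promoter_accessibility(cp$peaks, ann2)
  tt <- derive_tss_tts(ann2)$by_transcript
  pkdf <- cp$peaks$peaks
  for (g in sample(rownames(acc2), 5)) {
    rows <- tt[tt$gene_id == g, , drop = FALSE]
    hits <- character(0)
    for (i in seq_len(nrow(rows))) {
      ps <- if (rows$strand[i] == "+") rows$tss[i] - 1000 else rows$tss[i] + 1
      pe <- ps + 1000
      ov <- pkdf$start < pe & pkdf$end > ps & pkdf$chrom == rows$chrom[i]
      hits <- union(hits, pkdf$peak_id[ov])
    }
    expect_equal(acc2[g, ],
                 colSums(cp$peaks$counts[hits, , drop = FALSE]))
  }
})

test_that("expression/accessibility correlation handles edge cases", {
  e <- rbind(g1 = c(1, 2, 4, 8), g2 = c(1, 2, 3, 4))
  colnames(e) <- paste0("s", 1:4)
  a_prop <- e * 3
  r <- expression_accessibility_correlation(e, a_prop)
  expect_equal(r$r, c(1, 1), tolerance = 1e-6)
  a_const <- rbind(g1 = rep(2, 4), g2 = rep(3, 4))
  colnames(a_const) <- paste0("s", 1:4)
  expect_true(all(is.na(
    expression_accessibility_correlation(e, a_const)$r)))
  expect_error(
    expression_accessibility_correlation(e, unname(a_prop)[, 0]),
    "no shared samples")
  # invariance under a global positive rescaling of the expression
  r2 <- expression_accessibility_correlation(e * 100, a_prop)
  expect_equal(r$r, r2$r, tolerance = 1e-4)
  # fewer than 3 shared samples -> NA
  r3 <- expression_accessibility_correlation(e[, 1:2], a_prop[, 1:2])
  expect_true(all(is.na(r3$r)))
})

test_that("expression quartiles partition genes deterministically", {
  ex <- stats::setNames(1:8, paste0("g", 1:8))
  q <- quartile_accessibility(ex, ex)
  expect_equal(lengths(q$values), c(Q1 = 2, Q2 = 2, Q3 = 2, Q4 = 2))
  expect_true(all(diff(q$summary$median) > 0))
  # sizes differ by at most one for non-multiples of 4
  ex9 <- stats::setNames(c(1:9), paste0("g", 1:9))
  q9 <- quartile_accessibility(ex9, ex9)
  expect_lte(diff(range(lengths(q9$values))), 1)
  # tie-break by gene id is reproducible
  ext <- stats::setNames(rep(1, 8), paste0("g", 8:1))
  acc <- stats::setNames(1:8, paste0("g", 8:1))
  q1 <- quartile_accessibility(ext, acc)
  q2 <- quartile_accessibility(ext[sample(8)], acc)
  expect_equal(q1$values, q2$values)
  expect_error(quartile_accessibility(ex[1:3], ex[1:3]), "at least 4")
})

test_that("sample clustering uses 1 - r^2 with complete linkage", {
  v <- withr::with_seed(4, {
    base <- matrix(stats::rexp(200 * 6, 1 / 10), 200, 6)
    base[1:100, 4:6] <- base[1:100, 4:6] * 50   # two expression programs
    dimnames(base) <- list(paste0("g", 1:200), paste0("s", 1:6))
    base
  })
  # duplicated sample has distance 0 and merges first
  v2 <- cbind(v, s0 = v[, "s1"])
  cl <- cluster_samples(expression_table(v2))
  expect_equal(cl$dist["s0", "s1"], 0, tolerance = 1e-12)
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  expect_equal(diag(cl$dist), rep(0, 7), ignore_attr = TRUE)
  expect_equal(cl$dist, t(cl$dist))

  # planted two-group structure is recovered at k = 2
  cl2 <- cluster_samples(expression_table(v), k = 2)
  grp <- cl2$clusters
  expect_equal(length(unique(grp[c("s1", "s2", "s3")])), 1)
  expect_equal(length(unique(grp[c("s4", "s5", "s6")])), 1)
  expect_false(grp[["s1"]] == grp[["s4"]])
  expect_error(cluster_samples(expression_table(v), ortholog_features = "nope"),
               "empty")
})
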