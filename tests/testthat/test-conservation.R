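blocks_row <- function(score, t_start, t_chrom = "h1") {
  data.frame(query_id = "q", q_chrom = "c", q_start = 0, q_end = 100,
             t_chrom = t_chrom, t_start = t_start, t_end = t_start + 100,
             strand = "+", score = score)
}

test_that("best-hit selection is a deterministic argmax", {
  b1 <- blocks_row(5, 100)
  expect_equal(select_best_hit(b1)$score, 5)
  b <- rbind(blocks_row(5, 500), blocks_row(9, 300), blocks_row(9, 100))
  expect_equal(select_best_hit(b)$t_start, 100)   # tie -> smaller t_start
  b2 <- rbind(blocks_row(9, 100, "h2"), blocks_row(9, 100, "h1"))
  expect_equal(select_best_hit(b2)$t_chrom, "h1") # then smaller chrom id
  expect_error(select_best_hit(b[0, ]), "no blocks")
  for (s in 1:20) {
    bb <- withr::with_seed(s, {
      n <- sample(2:8, 1)
      data.frame(query_id = "q", q_chrom = "c", q_start = 0, q_end = 10,
                 t_chrom = "h1", t_start = sample(1000, n),
                 t_end = 2000, strand = "+",
                 score = sample(50, n, replace = TRUE))
    })
    bb$t_end <- bb$t_start + 10
    got <- select_best_hit(bb)
    top <- bb[bb$score == max(bb$score), ]
    expect_equal(got$score, max(bb$score))
    expect_equal(got$t_start, min(top$t_start))
  }
})

test_that("similarity clusters merge hits and flag ambiguity", {
  hits <- data.frame(species = c("cattle", "pig"),
                     feature_id = c("a", "b"), chrom = "h1",
                     start = c(0, 1000), end = c(100, 1100))
  cl <- build_similarity_clusters(hits)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$similarity_level, c(1, 1))

  hits2 <- data.frame(species = c("cattle", "pig"),
                      feature_id = c("a", "b"), chrom = "h1",
                      start = c(0, 50), end = c(100, 150))
  cl2 <- build_similarity_clusters(hits2)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$similarity_level, 2)
  expect_equal(cl2$start, 0)
  expect_equal(cl2$end, 150)

  hits3 <- data.frame(species = c("cattle", "cattle"),
                      feature_id = c("a", "b"), chrom = "h1",
                      start = c(0, 50), end = c(100, 150))
  cl3 <- build_similarity_clusters(hits3)
  expect_true(cl3$ambiguous)
  expect_true(is.na(cl3$similarity_level))

  # bookkeeping: members (ambiguous included) total the input hits, and
  # levels never exceed the number of species
  hits4 <- withr::with_seed(2, data.frame(
    species = sample(c("cattle", "goat", "pig", "chicken"), 60,
                     replace = TRUE),
    feature_id = paste0("f", 1:60), chrom = "h1",
    start = sample(0:5000, 60)))
  hits4$end <- hits4$start + 120
  cl4 <- build_similarity_clusters(hits4)
  expect_equal(sum(cl4$n_members), 60)
  expect_lte(max(cl4$similarity_level, na.rm = TRUE), 4)
})

test_that("chaining equals exhaustive subset enumeration", {
  # one block over half the query passes the default thresholds
  one <- data.frame(query_id = "q", q_chrom = "c", q_start = 0,
                    q_end = 6000, t_chrom = "h1", t_start = 100,
                    t_end = 6100, strand = "+", score = 4000)
  ch <- chain_blocks(one, query_length = 12000)
  expect_equal(ch$total_score, 4000)
  expect_equal(ch$query_coverage, 0.5)
  # the same block fails a 0.4 coverage cutoff on a longer query
  expect_null(chain_blocks(one, query_length = 20000))

  # target-crossing pairs are rejected: blocks 3+4 (score 900) cross on
  # the target, so the best chain mixes block 1 with block 4 (850)
  coll <- data.frame(query_id = "q", q_chrom = "c",
                     q_start = c(0, 500, 200, 600),
                     q_end = c(400, 900, 550, 950),
                     t_chrom = "h1",
                     t_start = c(100, 700, 5000, 1000),
                     t_end = c(500, 1100, 5350, 1350),
                     strand = "+", score = c(400, 400, 450, 450))
  ch2 <- chain_blocks(coll, query_length = 1000, min_coverage = 0.1,
                      min_score = 10, min_length = 10)
  expect_equal(ch2$total_score, 850)
  expect_equal(ch2$blocks$q_start, c(0, 600))

  # max-score chain equals exhaustive subset enumeration (thresholds off,
  # so the comparison is on the optimization itself)
  for (s in 1:60) {
    n <- withr::with_seed(1000 + s, sample(2:12, 1))
    b <- random_block_fixture(n, seed = 1000 + s)
    got <- chain_blocks(b, query_length = 6000, min_coverage = 0,
                        min_score = 0, min_length = 0)
    want <- oracle_chain_score(b, 6000, 0, 0, 0)
    expect_equal(got$total_score, want)
  }
})

test_that("syntenic lncRNA detection recovers exactly the planted triplets", {
  ms <- simulate_multispecies_annotation(seed = 31)
  tri <- detect_syntenic_lncrnas(ms$annotations, ms$orthology)
  expect_equal(nrow(tri), nrow(ms$planted))
  expect_setequal(tri$sp1_lnc, ms$planted$sp1)
  expect_setequal(tri$sp2_lnc, ms$planted$sp2)
  # the divergently-overlapping planted lncRNA (zero distance) is included
  expect_true(ms$planted$sp1[ms$planted$triplet == 1] %in% tri$sp1_lnc)

  # invariance under whole-genome coordinate reversal of one species
  rev_ann <- ms$annotations
  L <- max(rev_ann$sp2$exons$end) + 1000
  ex <- rev_ann$sp2$exons
  new_start <- L - ex$end
  ex$end <- L - ex$start
  ex$start <- new_start
  ex$strand <- ifelse(ex$strand == "+", "-", "+")
  rev_ann$sp2 <- annotation(ex, rev_ann$sp2$biotype)
  tri_rev <- detect_syntenic_lncrnas(rev_ann, ms$orthology)
  expect_setequal(tri_rev$sp1_lnc, tri$sp1_lnc)

  # shuffling the orthology (interleaving, so genome-adjacent genes are
  # never table-adjacent) destroys every triplet
  sh <- ms$orthology
  n <- nrow(sh)
  sh$sp2 <- sh$sp2[c(seq(1, n, 2), seq(2, n, 2))]
  expect_equal(nrow(detect_syntenic_lncrnas(ms$annotations, sh)), 0)
  expect_error(detect_syntenic_lncrnas(ms$annotations,
                                       ms$orthology[, 1:2]),
               "absent")

  # a gap holding two lncRNAs in every species is rejected
  two <- simulate_multispecies_annotation(n_species = 2, n_lnc = 4,
                                          n_planted_triplets = 2, seed = 7)
  tri2 <- detect_syntenic_lncrnas(two$annotations, two$orthology)
  expect_setequal(tri2$sp1_lnc, two$planted$sp1)
  # the two decoy lncRNAs share one gap and are never reported
  decoys <- setdiff(names(two$annotations$sp1$biotype)[
    two$annotations$sp1$biotype == "lncRNA"], two$planted$sp1)
  expect_length(decoys, 2)
  expect_false(any(decoys %in% tri2$sp1_lnc))
})

test_that("compartment conservation reproduces the worked example", {
  res <- compartment_conservation_summary(
    n_genes = 5728, p_a = c(0.695, 0.759, 0.764), obs_same = 3583)
  expect_equal(res$excess_percent_rounded, 49)
  expect_equal(res$excess_percent, 48.8, tolerance = 0.005)
  expect_true(is.na(res$chi2_A))

  # all species all-A: expectation equals observation, zero excess
  lab <- matrix("A", 100, 3)
  res2 <- compartment_conservation_test(lab)
  expect_equal(res2$excess_percent, 0)
  expect_true(is.na(res2$chi2_A))   # degenerate p_A = 1

  # label-table route agrees with the summary route
  lab3 <- withr::with_seed(3, matrix(sample(c("A", "B"), 3000, TRUE,
                                            prob = c(0.7, 0.3)), 1000, 3))
  r_tab <- compartment_conservation_test(lab3, combined = TRUE)
  r_sum <- compartment_conservation_summary(
    1000, colMeans(lab3 == "A"), r_tab$obs_same, r_tab$obs_same_A,
    r_tab$obs_same_B)
  expect_equal(r_tab$expected_same, r_sum$expected_same)
  expect_equal(r_tab$chi2_A, r_sum$chi2_A)
  expect_false(is.na(r_tab$p_combined))
  # NA labels are dropped before computing frequencies
  lab3na <- rbind(lab3, c("A", NA, "B"))
  expect_equal(compartment_conservation_test(lab3na)$n_genes, 1000)
})

test_that("permutation overlap test follows the add-one rule", {
  set.seed(NULL)
  a <- data.frame(chrom = "c1", start = c(0, 500, 900),
                  end = c(100, 650, 1000))
  sizes <- c(c1 = 100000)
  pt <- permutation_overlap_test(a, a, sizes, n_perm = 99, seed = 5)
  expect_equal(pt$observed_fraction, 1)
  expect_equal(pt$p_value, 1 / 100)

  pt0 <- permutation_overlap_test(a[0, ], a, sizes, n_perm = 99, seed = 5)
  expect_equal(pt0$observed_count, 0)
  expect_equal(pt0$p_value, 1)

  # reproducible given the seed; p never 0
  b <- data.frame(chrom = "c1", start = c(50, 2000), end = c(150, 2100))
  p1 <- permutation_overlap_test(a, b, sizes, n_perm = 199, seed = 7)
  p2 <- permutation_overlap_test(a, b, sizes, n_perm = 199, seed = 7)
  expect_identical(p1$perm_counts, p2$perm_counts)
  expect_gt(p1$p_value, 0)

  # observed count agrees with GenomicRanges on random sets
  for (s in 1:5) {
    qa <- withr::with_seed(s, data.frame(
      chrom = sample(c("c1", "c2"), 30, TRUE), start = sample(0:5000, 30)))
    qa$end <- qa$start + 200
    qb <- withr::with_seed(100 + s, data.frame(
      chrom = sample(c("c1", "c2"), 40, TRUE), start = sample(0:5000, 40)))
    qb$end <- qb$start + 150
    pt <- permutation_overlap_test(qa, qb, c(c1 = 10000, c2 = 10000),
                                   n_perm = 1, seed = 1)
    gr_a <- GenomicRanges::GRanges(qa$chrom,
                                   IRanges::IRanges(qa$start + 1, qa$end))
    gr_b <- GenomicRanges::GRanges(qb$chrom,
                                   IRanges::IRanges(qb$start + 1, qb$end))
    expect_equal(pt$observed_count,
                 sum(IRanges::overlapsAny(gr_b, gr_a)))
  }
  expect_error(permutation_overlap_test(
    data.frame(chrom = "c1", start = 0, end = 2e5), a, sizes),
    "longer than")
})

test_that("stratified score comparison detects shifts within levels", {
  set.seed(NULL)
  sc <- withr::with_seed(9, stats::rnorm(400))
  lv <- rep(1:4, each = 100)
  fl <- rep(c(TRUE, FALSE), 200)
  shifted <- sc + fl * 2
  out <- stratified_score_comparison(shifted, lv, fl)
  for (l in 1:4) {
    expect_gt(out$median[out$level == l & out$flagged],
              out$median[out$level == l & !out$flagged])
    expect_lt(out$p_value[out$level == l][1], 0.01)
  }
  expect_equal(tapply(out$n, out$level, sum),
               tapply(rep(1, 400), lv, sum), ignore_attr = TRUE)
  # empty group -> NA p-value
  out2 <- stratified_score_comparison(sc[1:10], rep(1, 10), rep(TRUE, 10))
  expect_true(is.na(out2$p_value[1]))
})
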