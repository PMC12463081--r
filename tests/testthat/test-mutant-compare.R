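# Loop matching across genotypes, HM fates, cross-classification and
# the association test.

test_that("loop matching is exact set algebra on canonical pairs", {
  wt <- make_loops(c(1L, 3L), c(2L, 4L))
  mut <- make_loops(c(3L, 5L), c(4L, 6L))
  m <- match_loops(wt, mut)
  expect_equal(m$disappeared$loop_id, "1:2")
  expect_equal(m$maintained$loop_id, "3:4")
  expect_equal(m$new$loop_id, "5:6")
  expect_equal(nrow(m$disappeared) + nrow(m$maintained), nrow(wt))
  expect_equal(nrow(m$new) + nrow(m$maintained), nrow(mut))

  ident <- match_loops(wt, wt)
  expect_equal(nrow(ident$disappeared), 0L)
  expect_equal(nrow(ident$new), 0L)

  empty <- match_loops(wt, wt[0, ])
  expect_equal(nrow(empty$disappeared), nrow(wt))

  # loops built on different fragment maps cannot be compared
  fa <- data.frame(fragment_id = 1:6, chrom = "c", start = 0:5, end = 1:6)
  fb <- data.frame(fragment_id = 1:6, chrom = "c", start = 0:5,
                   end = c(1:5, 99))
  expect_error(match_loops(make_loops(1L, 2L, fragments = fa),
                           make_loops(1L, 2L, fragments = fb)),
               "fragment maps")
})

test_that("HM change ratios respect the log2 threshold and its sign", {
  frags <- data.frame(fragment_id = 1:3, chrom = "chr1",
                      start = c(0, 100, 200), end = c(100, 200, 300))
  wt <- data.frame(chrom = "chr1", start = 0, end = 300, value = 4)
  mut <- data.frame(chrom = "chr1",
                    start = c(0, 100, 200), end = c(100, 200, 300),
                    value = c(2, 4, 8))  # halved, unchanged, doubled
  hm <- hm_change(1:3, frags, wt, mut, "H2Aub")
  expect_equal(hm$ratio, c(0.5, 1, 2))
  expect_equal(hm$decreased, c(TRUE, FALSE, FALSE))

  # monotonicity: lowering the threshold can only add decreased calls
  hm_strict <- hm_change(1:3, frags, wt, mut, "H2Aub", log2_threshold = 0.9)
  hm_loose <- hm_change(1:3, frags, wt, mut, "H2Aub", log2_threshold = 0.1)
  expect_true(all(hm_loose$decreased >= hm_strict$decreased))

  # no signal in either genotype: ratio 1, not decreased
  zero <- data.frame(chrom = "chr1", start = 0, end = 300, value = 0)
  hm0 <- hm_change(1:3, frags, zero, zero, "H2Aub")
  expect_equal(hm0$ratio, rep(1, 3))
  expect_false(any(hm0$decreased))

  # supplied differential regions override computed ratios
  hmr <- hm_change_from_regions(1:3, frags, regions("chr1", 150, 160),
                                "H2Aub")
  expect_equal(hmr$decreased, c(FALSE, TRUE, FALSE))
})

test_that("HM fate needs one decreased bait anchor and the relevant mark", {
  baits <- data.frame(fragment_id = c(1L, 2L, 3L),
                      bait_class = c("ONLY_H2AUB", "ONLY_H2AUB",
                                     "H2AUB_H3K27ME3"))
  loops <- make_loops(c(1L, 1L, 2L), c(2L, 3L, 3L))
  loops$baitness <- "BAIT_BAIT"
  loops$pcg_class <- c("ONLY_H2AUB", "BOTH", "BOTH")
  hm <- data.frame(fragment_id = c(1L, 2L, 3L, 3L),
                   mark = c("H2Aub", "H2Aub", "H2Aub", "H3K27me3"),
                   ratio = 1,
                   decreased = c(TRUE, FALSE, FALSE, TRUE))
  out <- hm_fate_at_anchors(loops, hm, baits)
  # loop (1,2): anchor 1 lost H2Aub -> Hl
  # loop (1,3): anchor 1 decreased -> Hl
  # loop (2,3): only K27 decrease at 3, relevant for a BOTH loop -> Hl
  expect_equal(out$hm_fate, c("Hl", "Hl", "Hl"))

  # the K27 decrease at anchor 3 is irrelevant for an only-H2Aub loop
  loops2 <- make_loops(2L, 3L)
  loops2$pcg_class <- "ONLY_H2AUB"
  expect_equal(hm_fate_at_anchors(loops2, hm, baits)$hm_fate, "Hm")

  # requiring both anchors: only the loop whose two anchors lost a
  # relevant mark stays Hl
  both <- hm_fate_at_anchors(loops, hm, baits, anchors_mode = "both")
  expect_equal(both$hm_fate, c("Hm", "Hl", "Hm"))

  # anchors without HM data are maintained, with a warning
  loops3 <- make_loops(1L, 2L)
  loops3$pcg_class <- "ONLY_H2AUB"
  expect_warning(out3 <- hm_fate_at_anchors(loops3, hm[0, ], baits),
                 "no HM data")
  expect_equal(out3$hm_fate, "Hm")
})

test_that("cross-classification partitions loops into the four cells", {
  loops <- make_loops(c(1L, 1L, 2L, 2L), c(2L, 3L, 3L, 4L))
  loops$loop_fate <- c("Ll", "Ll", "Lm", "Lm")
  loops$hm_fate <- c("Hl", "Hm", "Hl", "Hm")
  cc <- cross_classify(loops)
  expect_equal(cc$cells$proportion, rep(0.25, 4))
  expect_equal(sum(cc$counts), 4L)

  loops$loop_fate <- "Lm"; loops$hm_fate <- "Hm"
  cc2 <- cross_classify(loops)
  expect_equal(cc2$cells$proportion[cc2$cells$cell == "Lm/Hm"], 1)
  expect_equal(sum(cc2$cells$proportion), 1, tolerance = 1e-12)
})

test_that("association test matches the closed-form chi-squared", {
  # all expected counts are 20: statistic = 4 * 100/20 = 20
  res <- association_test(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  expect_false(res$haldane)

  # equal rows: exact independence
  res0 <- association_test(matrix(c(12, 30, 12, 30), 2, byrow = TRUE))
  expect_equal(res0$statistic, 0)

  # zero cells: Haldane-corrected odds ratio, strong rejection
  resz <- association_test(matrix(c(40, 0, 0, 40), 2, byrow = TRUE))
  expect_true(resz$haldane)
  expect_equal(resz$odds_ratio, (40.5 * 40.5) / (0.5 * 0.5))
  expect_lt(resz$p_value, 0.05)

  # Yates correction is available and shrinks the statistic
  resy <- association_test(matrix(c(30, 10, 10, 30), 2, byrow = TRUE),
                           correct = TRUE)
  expect_lt(resy$statistic, 20)

  # degenerate marginal: undefined test, flagged
  resd <- association_test(matrix(c(5, 7, 0, 0), 2, byrow = TRUE))
  expect_true(resd$degenerate)
  expect_true(is.na(resd$p_value))
})

test_that("coupled fate simulation recovers the planted association", {
  # generative odds ratio (0.8/0.2)/(0.2/0.8) = 16
  reject <- logical(100)
  or_ok <- logical(100)
  for (i in 1:100) {
    sim <- simulate_loop_fates(1000, 0.8, 0.2, 0.5, seed = 3000 + i)
    res <- association_test(attr(sim, "table"))
    reject[i] <- res$p_value < 0.05
    or_ok[i] <- res$odds_ratio >= 16 * 0.7 && res$odds_ratio <= 16 * 1.3
  }
  expect_gte(sum(reject), 99L)
  expect_gte(sum(or_ok), 90L)
})

test_that("the association test keeps its size under the null", {
  reject <- logical(200)
  for (i in 1:200) {
    sim <- simulate_loop_fates(1000, 0.5, 0.5, 0.5, seed = 7000 + i)
    res <- association_test(attr(sim, "table"))
    reject[i] <- res$p_value < 0.05
  }
  rate <- mean(reject)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("new loops are characterized against WT baits and anchors", {
  wt_baits <- data.frame(fragment_id = c(1L, 2L, 3L),
                         bait_class = c("ONLY_H2AUB", "H2AUB_H3K27ME3",
                                        "ONLY_H2AUB"))
  wt_anchors <- c(1L, 2L, 7L)
  new_loops <- make_loops(c(1L, 1L, 2L), c(2L, 9L, 8L))
  out <- characterize_new_loops(new_loops, wt_baits, wt_anchors)
  expect_equal(out$baitness$n[out$baitness$baitness == "BAIT_BAIT"], 1L)
  expect_equal(out$baitness$n[out$baitness$baitness == "BAIT_NONBAIT"], 2L)
  # fragments 8 and 9 were never baits nor WT anchors
  expect_setequal(out$new_nonbait_anchors$fragment_id, c(8, 9))
  expect_equal(
    out$new_nonbait_anchors$partner_class[
      out$new_nonbait_anchors$fragment_id == 9], "ONLY_H2AUB")
  expect_equal(
    out$new_nonbait_anchors$partner_class[
      out$new_nonbait_anchors$fragment_id == 8], "H2AUB_H3K27ME3")
})

test_that("venn counts equal brute-force set intersections", {
  set.seed(5)
  for (rep in 1:5) {
    sets <- list(A = sample(1:40, 20), B = sample(1:40, 15),
                 C = sample(1:40, 10))
    vc <- venn_counts(sets)
    for (el in unique(unlist(sets))) {
      pat <- paste(names(sets)[vapply(sets, function(s) el %in% s,
                                      logical(1))], collapse = "&")
      expect_true(pat %in% vc$pattern)
    }
    expect_equal(sum(vc$n), length(unique(unlist(sets))))
  }
})
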