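# Bait typing, baitness, PcG class, hub detection, loop geometry and
# anchor annotation.

frag10 <- data.frame(fragment_id = 1:10, chrom = "chr1",
                     start = seq(0, 4500, by = 500),
                     end = seq(500, 5000, by = 500))

test_that("baits are typed by H3K27me3 overlap", {
  b <- type_baits(1L, frag10, regions("chr1", 400, 450))
  expect_equal(b$bait_class, "H2AUB_H3K27ME3")
  # half-open: a peak starting at the fragment end does not overlap
  b <- type_baits(1L, frag10, regions("chr1", 500, 600))
  expect_equal(b$bait_class, "ONLY_H2AUB")
  b <- type_baits(1:3, frag10, regions("chr1", 0, 1)[0, ])
  expect_equal(b$bait_class, rep("ONLY_H2AUB", 3))
})

test_that("baitness partitions retained loops; no-bait loops are dropped", {
  baits <- data.frame(fragment_id = c(1L, 2L, 5L),
                      bait_class = c("ONLY_H2AUB", "H2AUB_H3K27ME3",
                                     "ONLY_H2AUB"))
  loops <- make_loops(c(1L, 1L, 7L), c(2L, 9L, 9L))
  expect_message(out <- classify_baitness(loops, baits), "1 loop")
  expect_equal(nrow(out), 2L)
  expect_equal(out$baitness, c("BAIT_BAIT", "BAIT_NONBAIT"))
  expect_equal(attr(out, "n_dropped"), 1L)
})

test_that("PcG class follows the anchor bait-class rule", {
  baits <- data.frame(fragment_id = c(1L, 2L, 3L, 4L),
                      bait_class = c("ONLY_H2AUB", "H2AUB_H3K27ME3",
                                     "ONLY_H2AUB", "H2AUB_H3K27ME3"))
  loops <- make_loops(c(1L, 1L, 2L, 2L, 1L),
                      c(2L, 3L, 4L, 9L, 9L))
  loops <- classify_baitness(loops, baits)
  loops <- classify_pcg(loops, baits)
  expect_equal(loops$pcg_class,
               c("BOTH",            # only x k27 bait
                 "ONLY_H2AUB",      # only x only
                 "H2AUB_H3K27ME3",  # k27 x k27
                 "H2AUB_H3K27ME3",  # k27 x non-bait
                 "ONLY_H2AUB"))     # only x non-bait
})

test_that("a Bait-Nonbait loop with a K27-marked non-bait anchor is
           reclassified and flagged", {
  baits <- data.frame(fragment_id = 1L, bait_class = "ONLY_H2AUB")
  loops <- classify_baitness(make_loops(1L, 9L), baits)
  # fragment 9 covers [4000,4500); mark it with K27
  loops <- classify_pcg(loops, baits, frag10, regions("chr1", 4100, 4200))
  expect_equal(loops$pcg_class, "H2AUB_H3K27ME3")
  expect_true(loops$nonbait_k27)
  # without peak info the literal bait-anchor rule applies
  loops2 <- classify_pcg(classify_baitness(make_loops(1L, 9L), baits), baits)
  expect_equal(loops2$pcg_class, "ONLY_H2AUB")
})

test_that("hub membership is one-step anchor sharing with Both-loops", {
  baits <- data.frame(
    fragment_id = 1:8,
    bait_class = rep(c("ONLY_H2AUB", "H2AUB_H3K27ME3"), each = 4))
  # L1=(1,5) BOTH; L2=(1,3) only-H2Aub shares anchor 1; L3=(2,4) does not
  loops <- make_loops(c(1L, 1L, 2L), c(5L, 3L, 4L))
  out <- classify_loops(loops, baits)
  expect_equal(out$final_class,
               c("PCGHUB_BOTH", "PCGHUB_ONLY_H2AUB", "PURE_ONLY_H2AUB"))

  # no Both-loops: everything is Pure
  out2 <- classify_loops(make_loops(c(1L, 2L), c(3L, 4L)), baits)
  expect_true(all(startsWith(out2$final_class, "PURE")))

  # two-step chains are not hub members by default, but are with
  # transitive closure
  loops3 <- make_loops(c(1L, 1L, 3L), c(5L, 3L, 2L))
  one_step <- classify_loops(loops3, baits)
  expect_equal(one_step$final_class[3], "PURE_ONLY_H2AUB")
  trans <- classify_loops(loops3, baits, transitive = TRUE)
  expect_equal(trans$final_class[3], "PCGHUB_ONLY_H2AUB")
})

test_that("five-way classification matches brute force on random sets", {
  set.seed(11)
  for (rep in 1:20) {
    inst <- random_loop_instance(sample(50:400, 1L))
    loops <- make_loops(inst$anchorA, inst$anchorB)
    got <- suppressMessages(classify_loops(loops, inst$baits))
    ora <- oracle_classify(inst$anchorA, inst$anchorB,
                           setNames(inst$baits$bait_class,
                                    inst$baits$fragment_id))
    expect_equal(nrow(got), nrow(ora))
    key_got <- paste(got$anchorA, got$anchorB)
    key_ora <- paste(ora$anchorA, ora$anchorB)
    m <- match(key_got, key_ora)
    expect_false(anyNA(m))
    expect_equal(got$baitness, ora$baitness[m])
    expect_equal(got$final_class, ora$final_class[m])
    # the five classes partition the retained loops
    expect_equal(sum(table(got$final_class)), nrow(got))
    expect_equal(sum(got$baitness %in% c("BAIT_BAIT", "BAIT_NONBAIT")),
                 nrow(got))
  }
})

test_that("adding a Both-loop never demotes a hub loop (monotonicity)", {
  set.seed(23)
  for (rep in 1:10) {
    inst <- random_loop_instance(150)
    loops <- make_loops(inst$anchorA, inst$anchorB)
    base <- suppressMessages(classify_loops(loops, inst$baits))
    only <- inst$baits$fragment_id[inst$baits$bait_class == "ONLY_H2AUB"]
    k27 <- inst$baits$fragment_id[inst$baits$bait_class == "H2AUB_H3K27ME3"]
    if (length(only) == 0L || length(k27) == 0L) next
    extra_a <- only[sample.int(length(only), 1L)]
    extra_b <- k27[sample.int(length(k27), 1L)]
    if (extra_a == extra_b) next
    key <- paste0(min(extra_a, extra_b), ":", max(extra_a, extra_b))
    if (key %in% loops$loop_id) next
    grown <- suppressMessages(classify_loops(
      make_loops(c(inst$anchorA, extra_a), c(inst$anchorB, extra_b)),
      inst$baits))
    m <- match(base$loop_id, grown$loop_id)
    expect_true(all(grown$hub_member[m] >= base$hub_member))
  }
})

test_that("shared bait anchors between baitness classes match set algebra", {
  baits <- data.frame(fragment_id = 1:4,
                      bait_class = rep("ONLY_H2AUB", 4))
  # anchor 1 forms a Bait-Bait and a Bait-Nonbait loop; 3 only Bait-Bait
  loops <- classify_baitness(make_loops(c(1L, 1L, 3L), c(2L, 9L, 4L)), baits)
  ov <- bait_anchor_overlap(loops, baits)
  expect_equal(sort(ov$bait_bait_anchors), c(1, 2, 3, 4))
  expect_equal(ov$bait_nonbait_anchors, 1)
  expect_equal(ov$n_shared, 1L)
  expect_equal(ov$n_bait_bait_only, 3L)
  expect_equal(ov$n_bait_nonbait_only, 0L)
})

test_that("loop length is the midpoint distance; trans pairs are flagged", {
  frags <- data.frame(fragment_id = 1:4,
                      chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(0, 100, 200, 0), end = c(100, 200, 300, 500))
  ll <- loop_length(make_loops(c(1L, 1L, 1L), c(3L, 2L, 4L)), frags)
  expect_equal(ll$length[1], 200)   # midpoints 50 and 250
  expect_equal(ll$length[2], 100)   # adjacent fragments
  expect_true(is.na(ll$length[3]))
  expect_true(ll$trans[3])
})

test_that("gene loop span is the max pairwise midpoint distance per side", {
  frags <- data.frame(fragment_id = 1:6, chrom = "chr1",
                      start = c(0, 900, 1900, 2900, 9900, 10100),
                      end = c(200, 1100, 2100, 3100, 10100, 10300))
  gene <- regions("chr1", 9900, 10300, gene_id = "g")
  # other anchors at midpoints 100, 1000, 2000, 3000 (all left of gene)
  loops <- make_loops(c(5L, 5L, 6L), c(2L, 3L, 4L))
  sp <- gene_loop_span(loops, gene, frags)
  expect_equal(sp$side, "left")
  expect_equal(sp$span, 2000)  # 3000 - 1000
  expect_equal(sp$n_anchors, 3L)

  # a single other anchor on a side has span 0
  sp1 <- gene_loop_span(make_loops(c(5L, 5L), c(2L, 1L)), gene, frags)
  expect_equal(sp1$span, 900)  # midpoints 100 and 1000
  # fewer than two anchored loops: no record
  expect_null(gene_loop_span(make_loops(5L, 2L), gene, frags))
})

test_that("anchor features follow exon > intron > promoter > intergenic", {
  frags <- data.frame(fragment_id = 1:4, chrom = "chr1",
                      start = c(1000, 1900, 4300, 8000),
                      end = c(1200, 2100, 4500, 8200))
  genes <- regions("chr1", 1000, 3000, strand = "+", gene_id = "g1")
  exons <- regions("chr1", c(1000, 2500), c(1500, 3000), gene_id = "g1")
  # promoter of g1 on + strand: [0,1000); fragment 3 at [4300,4500) is
  # intergenic; a fragment overlapping exon and intron is exon
  frags2 <- rbind(frags, data.frame(fragment_id = 5L, chrom = "chr1",
                                    start = 1400, end = 1700))
  lab <- annotate_anchor_features(c(1L, 5L, 3L, 4L), frags2, genes, exons)
  expect_equal(lab, c("exon", "exon", "intergenic", "intergenic"))
  lab2 <- annotate_anchor_features(2L, frags2, genes, exons)
  expect_equal(lab2, "intron")
  # anchor 500 bp upstream of the + strand gene start
  frags3 <- rbind(frags2, data.frame(fragment_id = 6L, chrom = "chr1",
                                     start = 400, end = 600))
  expect_equal(annotate_anchor_features(6L, frags3, genes, exons),
               "promoter")

  dist <- feature_distribution(c("exon", "exon", "intergenic"),
                               c("bait", "bait", "nonbait"))
  expect_equal(dist$proportion[dist$group == "bait" & dist$feature == "exon"],
               1)
})
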