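# Bait typing and the five-way classification of H2Aub loops.
#
# A bait is an H2Aub-captured restriction fragment; baits split into
# only-H2Aub and H2Aub/H3K27me3 baits by H3K27me3 overlap. Loops are
# unordered pairs of anchor fragments with at least one bait anchor
# (the capture principle). Both-loops join the two bait types and seed
# the PcG hub; loops sharing an anchor with a Both-loop are hub
# members, the rest are Pure.

BAIT_CLASSES <- c("ONLY_H2AUB", "H2AUB_H3K27ME3")
FINAL_CLASSES <- c("PCGHUB_BOTH", "PCGHUB_ONLY_H2AUB",
                   "PCGHUB_H2AUB_H3K27ME3", "PURE_ONLY_H2AUB",
                   "PURE_H2AUB_H3K27ME3")

#' Interaction-caller weight settings (passthrough metadata)
#'
#' The statistical loop calling that produces the input loop tables is
#' performed upstream by a dedicated caller (CHiCAGO); this package
#' only consumes its output. The weight settings used for
#' Arabidopsis-scale capture designs are recorded here verbatim so a
#' run manifest can carry them; they are never used in computation.
#'
#' @return Named list of CHiCAGO weight parameters.
#' @export
chicago_weights <- function() {
  list(weightAlpha = 13.5319239, weightBeta = -1.3100426,
       weightGamma = -10.3516115, weightDelta = 0.1635212)
}

#' Type bait fragments by H3K27me3 co-marking
#'
#' Bait fragments overlapping at least one H3K27me3 peak are
#' `H2AUB_H3K27ME3` baits; the rest are `ONLY_H2AUB`. The two classes
#' partition the bait set.
#'
#' @param bait_ids Fragment ids of bait fragments (typically from
#'   [map_regions_to_fragments()] over H2Aub peaks).
#' @param fragments Fragment map.
#' @param k27_peaks H3K27me3 peak intervals.
#' @param min_overlap Minimum shared bases (default 1).
#' @return Data.frame `fragment_id`, `bait_class`.
#' @export
type_baits <- function(bait_ids, fragments, k27_peaks, min_overlap = 1L) {
  frags <- fragments_by_id(fragments, bait_ids)
  marked <- rep(FALSE, length(bait_ids))
  if (!is.null(k27_peaks) && nrow(k27_peaks) > 0L && length(bait_ids) > 0L) {
    ov <- find_region_overlaps(frags, k27_peaks, min_overlap = min_overlap)
    marked[unique(ov$query)] <- TRUE
  }
  data.frame(fragment_id = bait_ids,
             bait_class = ifelse(marked, "H2AUB_H3K27ME3", "ONLY_H2AUB"),
             stringsAsFactors = FALSE)
}

#' Build a canonical loop table from anchor fragment ids
#'
#' Loop identity is the unordered fragment pair; anchors are stored in
#' canonical order (lower fragment id first, which is genomic order
#' since ids follow chromosome/start order). Self-pairs are an error.
#'
#' @param anchor_a,anchor_b Fragment id vectors.
#' @param score Optional interaction score.
#' @param fragments Optional fragment map; when given, a map signature
#'   is attached so that loop sets from different maps cannot be
#'   compared by accident.
#' @return Loop data.frame `loop_id`, `anchorA`, `anchorB`, `score`.
#' @export
make_loops <- function(anchor_a, anchor_b, score = NA_real_,
                       fragments = NULL) {
  if (length(anchor_a) != length(anchor_b)) {
    stop("anchor vectors must have equal length")
  }
  if (any(anchor_a == anchor_b)) {
    stop("a loop must join two distinct anchor fragments")
  }
  a <- pmin(anchor_a, anchor_b)
  b <- pmax(anchor_a, anchor_b)
  out <- data.frame(loop_id = paste0(a, ":", b), anchorA = a, anchorB = b,
                    score = rep_len(score, length(a)),
                    stringsAsFactors = FALSE)
  if (!is.null(fragments)) {
    attr(out, "fragment_map") <- fragment_map_signature(fragments)
  }
  out
}

fragment_map_signature <- function(fragments) {
  sprintf("%d:%.0f", nrow(fragments), sum(as.numeric(fragments$end)))
}

#' Map a BEDPE-like anchor-pair table to fragment loops
#'
#' Each anchor interval is assigned to the fragment it overlaps most
#' (ties broken toward the lower fragment id), then the pair is
#' canonicalized with [make_loops()].
#'
#' @param loop_regions Data.frame with `chromA,startA,endA,chromB,
#'   startB,endB` and optional `score`.
#' @param fragments Fragment map.
#' @return Canonical loop data.frame.
#' @export
loops_from_regions <- function(loop_regions, fragments) {
  check_fragments(fragments)
  assign_one <- function(chrom, start, end) {
    reg <- data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE)
    ov <- find_region_overlaps(reg, fragments)
    if (nrow(ov) == 0L) {
      stop("anchor ", chrom[1], ":", start[1], "-", end[1],
           " overlaps no fragment")
    }
    ov <- ov[order(ov$query, -ov$overlap_bp, ov$subject), , drop = FALSE]
    best <- ov[!duplicated(ov$query), , drop = FALSE]
    if (nrow(best) != nrow(reg)) {
      miss <- setdiff(seq_len(nrow(reg)), best$query)[1L]
      stop("anchor ", chrom[miss], ":", start[miss], "-", end[miss],
           " overlaps no fragment")
    }
    fragments$fragment_id[best$subject[order(best$query)]]
  }
  a <- assign_one(loop_regions$chromA, loop_regions$startA, loop_regions$endA)
  b <- assign_one(loop_regions$chromB, loop_regions$startB, loop_regions$endB)
  score <- if ("score" %in% names(loop_regions)) loop_regions$score else NA_real_
  make_loops(a, b, score, fragments)
}

#' Classify loops as Bait-Bait or Bait-Nonbait
#'
#' Loops with two bait anchors are `BAIT_BAIT`, with exactly one bait
#' anchor `BAIT_NONBAIT`. Loops with no bait anchor cannot be captured
#' by the bait library and are dropped with a logged count (attribute
#' `n_dropped` and a message).
#'
#' @param loops Loop data.frame.
#' @param baits Bait table from [type_baits()].
#' @return Loops with a `baitness` column.
#' @export
classify_baitness <- function(loops, baits) {
  in_bait <- function(x) x %in% baits$fragment_id
  nb <- in_bait(loops$anchorA) + in_bait(loops$anchorB)
  dropped <- sum(nb == 0L)
  if (dropped > 0L) {
    message("Dropped ", dropped, " loop(s) with no bait anchor")
  }
  out <- loops[nb > 0L, , drop = FALSE]
  out$baitness <- ifelse(nb[nb > 0L] == 2L, "BAIT_BAIT", "BAIT_NONBAIT")
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  attr(out, "fragment_map") <- attr(loops, "fragment_map")
  out
}

# bait class per anchor, NA for non-baits
.anchor_class <- function(ids, baits) {
  baits$bait_class[match(ids, baits$fragment_id)]
}

#' Assign the three-way PcG class of each loop
#'
#' `BOTH` iff one anchor is an only-H2Aub bait and the other an
#' H2Aub/H3K27me3 bait; `ONLY_H2AUB` iff every bait anchor is
#' only-H2Aub and no anchor is an H2Aub/H3K27me3 bait; `H2AUB_H3K27ME3`
#' iff at least one bait anchor is H2Aub/H3K27me3 and no bait anchor is
#' only-H2Aub. When the fragment map and H3K27me3 peaks are supplied, a
#' Bait-Nonbait loop whose non-bait anchor overlaps an H3K27me3 peak is
#' reclassified `H2AUB_H3K27ME3` (at least one anchor is
#' H3K27me3-enriched) and flagged in the `nonbait_k27` column.
#'
#' @param loops Loops with `baitness` assigned.
#' @param baits Bait table.
#' @param fragments Optional fragment map (for the non-bait H3K27me3
#'   check).
#' @param k27_peaks Optional H3K27me3 peaks.
#' @return Loops with `pcg_class` (and `nonbait_k27`) columns.
#' @export
classify_pcg <- function(loops, baits, fragments = NULL, k27_peaks = NULL) {
  if (!"baitness" %in% names(loops)) {
    stop("run classify_baitness() first")
  }
  ca <- .anchor_class(loops$anchorA, baits)
  cb <- .anchor_class(loops$anchorB, baits)
  n_only <- (ca %in% "ONLY_H2AUB") + (cb %in% "ONLY_H2AUB")
  n_k27 <- (ca %in% "H2AUB_H3K27ME3") + (cb %in% "H2AUB_H3K27ME3")
  pcg <- ifelse(n_only >= 1L & n_k27 >= 1L, "BOTH",
                ifelse(n_k27 >= 1L, "H2AUB_H3K27ME3", "ONLY_H2AUB"))
  nonbait_k27 <- rep(FALSE, nrow(loops))
  if (!is.null(fragments) && !is.null(k27_peaks) && nrow(loops) > 0L) {
    nb_id <- ifelse(is.na(ca), loops$anchorA,
                    ifelse(is.na(cb), loops$anchorB, NA_real_))
    has_nb <- which(!is.na(nb_id))
    if (length(has_nb) > 0L && nrow(k27_peaks) > 0L) {
      frags <- fragments_by_id(fragments, nb_id[has_nb])
      ov <- find_region_overlaps(frags, k27_peaks)
      nonbait_k27[has_nb[unique(ov$query)]] <- TRUE
    }
    pcg[nonbait_k27 & pcg == "ONLY_H2AUB"] <- "H2AUB_H3K27ME3"
  }
  loops$pcg_class <- pcg
  loops$nonbait_k27 <- nonbait_k27
  loops
}

#' Detect PcG hub membership and assign the five-way final class
#'
#' The hub seed set is every anchor of a `BOTH` loop. A non-BOTH loop
#' is a hub member iff it shares at least one anchor fragment with the
#' seed set (one-step sharing). `BOTH` loops are hub members by
#' definition. With `transitive = TRUE` the seed set is instead grown
#' to the full anchor-sharing connected component of the BOTH loops.
#' With `share_anchors = "bait"` only a loop's bait anchors are
#' consulted when testing sharing.
#'
#' The final classes
#' `PCGHUB_BOTH, PCGHUB_ONLY_H2AUB, PCGHUB_H2AUB_H3K27ME3,
#' PURE_ONLY_H2AUB, PURE_H2AUB_H3K27ME3` partition the loop set.
#'
#' @param loops Loops with `pcg_class` assigned.
#' @param share_anchors `"any"` (default) or `"bait"`.
#' @param transitive Grow the hub transitively (default `FALSE`).
#' @param baits Bait table; required for `share_anchors = "bait"`.
#' @return Loops with `hub_member` and `final_class` columns.
#' @export
detect_pcg_hub <- function(loops, share_anchors = c("any", "bait"),
                           transitive = FALSE, baits = NULL) {
  share_anchors <- match.arg(share_anchors)
  if (!"pcg_class" %in% names(loops)) stop("run classify_pcg() first")
  if (share_anchors == "bait" && is.null(baits)) {
    stop("share_anchors = 'bait' requires the bait table")
  }
  is_both <- loops$pcg_class == "BOTH"
  seed <- unique(c(loops$anchorA[is_both], loops$anchorB[is_both]))
  test_a <- loops$anchorA
  test_b <- loops$anchorB
  if (share_anchors == "bait") {
    test_a[!test_a %in% baits$fragment_id] <- NA_real_
    test_b[!test_b %in% baits$fragment_id] <- NA_real_
  }
  member <- is_both | (test_a %in% seed) | (test_b %in% seed)
  if (transitive) {
    repeat {
      seed2 <- unique(c(seed, test_a[member], test_b[member]))
      seed2 <- seed2[!is.na(seed2)]
      new_member <- is_both | (test_a %in% seed2) | (test_b %in% seed2)
      if (length(seed2) == length(seed) && all(new_member == member)) break
      seed <- seed2
      member <- new_member
    }
  }
  loops$hub_member <- member
  loops$final_class <- ifelse(
    is_both, "PCGHUB_BOTH",
    ifelse(loops$pcg_class == "ONLY_H2AUB",
           ifelse(member, "PCGHUB_ONLY_H2AUB", "PURE_ONLY_H2AUB"),
           ifelse(member, "PCGHUB_H2AUB_H3K27ME3", "PURE_H2AUB_H3K27ME3")))
  loops
}

#' Full loop classification
#'
#' Convenience wrapper chaining [classify_baitness()], [classify_pcg()]
#' and [detect_pcg_hub()].
#'
#' @inheritParams classify_pcg
#' @inheritParams detect_pcg_hub
#' @return Fully classified loop table.
#' @export
classify_loops <- function(loops, baits, fragments = NULL, k27_peaks = NULL,
                           share_anchors = "any", transitive = FALSE) {
  loops <- classify_baitness(loops, baits)
  loops <- classify_pcg(loops, baits, fragments, k27_peaks)
  detect_pcg_hub(loops, share_anchors = share_anchors,
                 transitive = transitive, baits = baits)
}

#' Genomic length of loops
#'
#' Loop length is the distance between the midpoints of the two anchor
#' fragments. Trans-chromosomal pairs have no genomic length; they are
#' flagged and return `NA`.
#'
#' @param loops Loop data.frame.
#' @param fragments Fragment map.
#' @return Data.frame `loop_id`, `length`, `trans`.
#' @export
loop_length <- function(loops, fragments) {
  fa <- fragments_by_id(fragments, loops$anchorA)
  fb <- fragments_by_id(fragments, loops$anchorB)
  trans <- fa$chrom != fb$chrom
  len <- abs(region_midpoints(fb) - region_midpoints(fa))
  len[trans] <- NA_real_
  data.frame(loop_id = loops$loop_id, length = len, trans = trans,
             stringsAsFactors = FALSE)
}

#' Loop span of a gene
#'
#' For a gene carrying at least two loops, the partner ("other")
#' anchors of its loops are split by direction — genomic left vs right
#' of the gene — and the span of each side is the maximum pairwise
#' distance among that side's anchor midpoints (`mode = "pairwise"`,
#' default) or the maximum distance from the gene boundary
#' (`mode = "from_gene"`). A smaller span means the gene's interactions
#' are more concentrated. Genes with fewer than two anchored loops
#' yield no record.
#'
#' @param loops Loop data.frame.
#' @param gene One-row gene interval data.frame with `gene_id`.
#' @param fragments Fragment map.
#' @param mode Span definition (see above).
#' @return Data.frame `gene_id`, `side`, `n_anchors`, `span`, or `NULL`
#'   when the gene has fewer than two loops.
#' @export
gene_loop_span <- function(loops, gene, fragments,
                           mode = c("pairwise", "from_gene")) {
  mode <- match.arg(mode)
  stopifnot(nrow(gene) == 1L)
  fa <- fragments_by_id(fragments, loops$anchorA)
  fb <- fragments_by_id(fragments, loops$anchorB)
  on_a <- overlaps(fa, gene)
  on_b <- overlaps(fb, gene)
  anchored <- on_a | on_b
  if (sum(anchored) < 2L) return(NULL)
  # partner anchor of each anchored loop (loops with both anchors on
  # the gene contribute no outside anchor)
  other <- ifelse(on_a & !on_b, loops$anchorB,
                  ifelse(on_b & !on_a, loops$anchorA, NA_real_))
  other <- other[anchored & !is.na(other)]
  if (length(other) == 0L) return(NULL)
  fo <- fragments_by_id(fragments, other)
  fo <- fo[fo$chrom == gene$chrom, , drop = FALSE]
  mids <- region_midpoints(fo)
  res <- list()
  for (side in c("left", "right")) {
    m <- if (side == "left") mids[mids < gene$start] else mids[mids >= gene$end]
    if (length(m) == 0L) next
    span <- if (mode == "pairwise") max(m) - min(m) else
      max(if (side == "left") gene$start - m else m - gene$end)
    res[[side]] <- data.frame(gene_id = gene$gene_id, side = side,
                              n_anchors = length(m), span = span,
                              stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(NULL)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Annotate anchors with genomic features
#'
#' Labels each anchor fragment `exon`, `intron`, `promoter` or
#' `intergenic` on at least 1 bp overlap, with precedence
#' exon > intron > promoter > intergenic: an anchor overlapping any
#' exon is `exon`; otherwise overlapping any gene body is `intron`;
#' otherwise overlapping any promoter window is `promoter`.
#'
#' @param anchor_ids Fragment ids to annotate.
#' @param fragments Fragment map.
#' @param genes Gene intervals (`gene_id`, `strand`).
#' @param exons Exon intervals.
#' @param promoter_width Promoter window in bp (default 1000).
#' @return Character vector of labels, parallel to `anchor_ids`.
#' @export
annotate_anchor_features <- function(anchor_ids, fragments, genes, exons,
                                     promoter_width = 1000L) {
  frags <- fragments_by_id(fragments, anchor_ids)
  hit <- function(subject) {
    out <- rep(FALSE, nrow(frags))
    if (!is.null(subject) && nrow(subject) > 0L) {
      ov <- find_region_overlaps(frags, subject)
      out[unique(ov$query)] <- TRUE
    }
    out
  }
  in_exon <- hit(exons)
  in_gene <- hit(genes)
  in_prom <- hit(promoter_regions(genes, promoter_width))
  ifelse(in_exon, "exon",
         ifelse(in_gene, "intron",
                ifelse(in_prom, "promoter", "intergenic")))
}

#' Feature distribution per anchor class
#'
#' @param labels Feature labels (from [annotate_anchor_features()]).
#' @param groups Grouping vector (e.g. bait vs non-bait), parallel to
#'   `labels`.
#' @return Data.frame `group`, `feature`, `n`, `proportion`.
#' @export
feature_distribution <- function(labels, groups) {
  stopifnot(length(labels) == length(groups))
  tab <- as.data.frame(table(group = groups, feature = labels),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tot <- tapply(tab$n, tab$group, sum)
  tab$proportion <- tab$n / as.numeric(tot[tab$group])
  tab
}

#' Bait anchors shared between Bait-Bait and Bait-Nonbait loops
#'
#' Venn-style counts of the bait anchors forming each loop baitness
#' class: how many bait anchors drive only Bait-Bait loops, only
#' Bait-Nonbait loops, or both.
#'
#' @param loops Loops with `baitness` assigned.
#' @param baits Bait table.
#' @return List with the two anchor sets and the three counts.
#' @export
bait_anchor_overlap <- function(loops, baits) {
  anchors_of <- function(cls) {
    sub <- loops[loops$baitness == cls, , drop = FALSE]
    ids <- c(sub$anchorA, sub$anchorB)
    unique(ids[ids %in% baits$fragment_id])
  }
  bb <- anchors_of("BAIT_BAIT")
  bn <- anchors_of("BAIT_NONBAIT")
  list(bait_bait_anchors = bb, bait_nonbait_anchors = bn,
       n_bait_bait_only = length(setdiff(bb, bn)),
       n_shared = length(intersect(bb, bn)),
       n_bait_nonbait_only = length(setdiff(bn, bb)))
}
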