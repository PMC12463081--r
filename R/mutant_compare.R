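# Wild-type versus mutant comparison: loop fates (disappeared /
# maintained / new), histone-modification fates at bait anchors,
# the Ll-Lm x Hl-Hm cross-classification, association testing, and
# characterization of newly formed loops.

FATE_CELLS <- c("Ll/Hl", "Ll/Hm", "Lm/Hl", "Lm/Hm")

#' Match loops between two genotypes
#'
#' Loops are matched on their canonical fragment-pair identity.
#' Disappeared loops are present in WT but absent in the mutant;
#' maintained loops are present in both; new loops are exclusive to
#' the mutant. Loop sets built on different fragment maps cannot be
#' compared and raise an error.
#'
#' @param wt_loops,mut_loops Canonical loop data.frames.
#' @return List of data.frames `disappeared`, `maintained` (WT rows),
#'   `new` (mutant rows).
#' @export
match_loops <- function(wt_loops, mut_loops) {
  mw <- attr(wt_loops, "fragment_map")
  mm <- attr(mut_loops, "fragment_map")
  if (!is.null(mw) && !is.null(mm) && !identical(mw, mm)) {
    stop("loop sets are defined on different fragment maps")
  }
  in_mut <- wt_loops$loop_id %in% mut_loops$loop_id
  in_wt <- mut_loops$loop_id %in% wt_loops$loop_id
  list(disappeared = wt_loops[!in_mut, , drop = FALSE],
       maintained = wt_loops[in_mut, , drop = FALSE],
       new = mut_loops[!in_wt, , drop = FALSE])
}

#' Annotate WT loops with their loop fate
#'
#' @param wt_loops WT loop data.frame.
#' @param matched Result of [match_loops()].
#' @return `wt_loops` with a `loop_fate` column (`Ll` lost, `Lm`
#'   maintained).
#' @export
loop_fates <- function(wt_loops, matched) {
  wt_loops$loop_fate <- ifelse(
    wt_loops$loop_id %in% matched$maintained$loop_id, "Lm", "Ll")
  wt_loops
}

#' Mutant/WT occupancy change at fragments
#'
#' Computes the mutant/WT ratio of mean occupancy over each fragment
#' and calls a decrease when `log2(ratio) < -log2_threshold` (the
#' differential-binding convention of an absolute log2 fold change
#' above the threshold, with the decreasing sign). A tiny pseudocount
#' keeps the ratio defined when a fragment carries no signal in either
#' genotype (such fragments get ratio 1, not decreased).
#'
#' @param fragment_ids Fragments to evaluate.
#' @param fragments Fragment map.
#' @param wt_track,mut_track Signal tracks (bedGraph data.frames).
#' @param mark Mark name recorded in the output (e.g. `"H2Aub"`).
#' @param log2_threshold Decrease threshold on |log2 ratio|
#'   (default 0.2).
#' @return Data.frame `fragment_id`, `mark`, `ratio`, `decreased`.
#' @export
hm_change <- function(fragment_ids, fragments, wt_track, mut_track, mark,
                      log2_threshold = 0.2) {
  frags <- fragments_by_id(fragments, fragment_ids)
  occ_wt <- mean_occupancy(wt_track, frags)
  occ_mut <- mean_occupancy(mut_track, frags)
  eps <- 1e-9
  ratio <- (occ_mut + eps) / (occ_wt + eps)
  data.frame(fragment_id = fragment_ids, mark = mark, ratio = ratio,
             decreased = log2(ratio) < -log2_threshold,
             stringsAsFactors = FALSE)
}

#' Mark decreased calls from a supplied differential-region list
#'
#' Alternative to [hm_change()] when decreased regions come from an
#' external differential-binding caller: a fragment is decreased iff it
#' overlaps a supplied region.
#'
#' @param fragment_ids Fragments to evaluate.
#' @param fragments Fragment map.
#' @param decreased_regions Interval data.frame of decreased regions.
#' @param mark Mark name.
#' @return Data.frame as in [hm_change()], with `ratio = NA`.
#' @export
hm_change_from_regions <- function(fragment_ids, fragments,
                                   decreased_regions, mark) {
  frags <- fragments_by_id(fragments, fragment_ids)
  dec <- rep(FALSE, length(fragment_ids))
  if (!is.null(decreased_regions) && nrow(decreased_regions) > 0L) {
    ov <- find_region_overlaps(frags, decreased_regions)
    dec[unique(ov$query)] <- TRUE
  }
  data.frame(fragment_id = fragment_ids, mark = mark, ratio = NA_real_,
             decreased = dec, stringsAsFactors = FALSE)
}

#' Histone-modification fate at loop anchors
#'
#' A loop's HM fate is `Hl` (lost) when at least one of its bait
#' anchors shows a decreased relevant mark, else `Hm` (maintained).
#' Mark relevance follows the loop's PcG class: for only-H2Aub loops
#' only an H2Aub decrease counts; for H3K27me3-involved loops (BOTH or
#' H2Aub/H3K27me3 class) a decrease of either mark counts, restricted
#' at each anchor to the marks that anchor actually carries (an
#' only-H2Aub bait has no H3K27me3 to lose). With
#' `anchors_mode = "both"` every bait anchor must be decreased. Bait
#' anchors missing a relevant mark in `hm_changes` are treated as
#' maintained, with a warning.
#'
#' @param loops Classified WT loops (needs `pcg_class`).
#' @param hm_changes HM change table ([hm_change()] rows for one or
#'   both marks, concatenated; `mark` must use `"H2Aub"` /
#'   `"H3K27me3"`).
#' @param baits Bait table.
#' @param anchors_mode `"any"` (default) or `"both"`.
#' @return `loops` with an `hm_fate` column (`Hl`/`Hm`).
#' @export
hm_fate_at_anchors <- function(loops, hm_changes, baits,
                               anchors_mode = c("any", "both")) {
  anchors_mode <- match.arg(anchors_mode)
  if (!"pcg_class" %in% names(loops)) stop("loops need pcg_class")
  key <- paste(hm_changes$fragment_id, hm_changes$mark)
  dec <- setNames(hm_changes$decreased, key)
  bait_class <- setNames(baits$bait_class, baits$fragment_id)
  missing_any <- FALSE
  anchor_decreased <- function(id, loop_marks) {
    # restrict to the marks this anchor carries
    marks <- if (identical(bait_class[[as.character(id)]], "ONLY_H2AUB"))
      intersect(loop_marks, "H2Aub") else loop_marks
    k <- paste(id, marks)
    known <- k %in% names(dec)
    if (any(!known)) missing_any <<- TRUE
    any(dec[k[known]])
  }
  marks_for <- lapply(loops$pcg_class, function(cl) {
    if (identical(cl, "ONLY_H2AUB")) "H2Aub" else c("H2Aub", "H3K27me3")
  })
  fate <- character(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    ids <- c(loops$anchorA[i], loops$anchorB[i])
    ids <- ids[ids %in% baits$fragment_id]
    d <- vapply(ids, anchor_decreased, logical(1), loop_marks = marks_for[[i]])
    hl <- if (anchors_mode == "any") any(d) else length(d) > 0L && all(d)
    fate[i] <- if (hl) "Hl" else "Hm"
  }
  if (missing_any) {
    warning("some bait anchors had no HM data; treated as maintained")
  }
  loops$hm_fate <- fate
  loops
}

#' Cross-classify loops by loop fate and HM fate
#'
#' Every WT loop falls in exactly one of the four cells Ll/Hl, Ll/Hm,
#' Lm/Hl, Lm/Hm; counts sum to the number of loops and proportions to
#' 1.
#'
#' @param loops Loops with `loop_fate` and `hm_fate` columns.
#' @return List with the 2x2 `counts` matrix (rows = loop fate,
#'   columns = HM fate) and a tidy `cells` data.frame.
#' @export
cross_classify <- function(loops) {
  if (!all(c("loop_fate", "hm_fate") %in% names(loops))) {
    stop("loops need loop_fate and hm_fate columns")
  }
  counts <- table(factor(loops$loop_fate, levels = c("Ll", "Lm")),
                  factor(loops$hm_fate, levels = c("Hl", "Hm")))
  counts <- matrix(as.integer(counts), nrow = 2,
                   dimnames = list(loop_fate = c("Ll", "Lm"),
                                   hm_fate = c("Hl", "Hm")))
  cell <- paste0(loops$loop_fate, "/", loops$hm_fate)
  tab <- table(factor(cell, levels = FATE_CELLS))
  cells <- data.frame(cell = FATE_CELLS, n = as.integer(tab),
                      proportion = as.integer(tab) / max(1L, nrow(loops)),
                      stringsAsFactors = FALSE)
  list(counts = counts, cells = cells)
}

#' Chi-squared association test on a 2x2 table
#'
#' Pearson chi-squared without continuity correction by default
#' (configurable Yates), plus the odds ratio with the Haldane 0.5
#' correction applied to all cells when any cell is zero. A zero row or
#' column marginal leaves the test undefined (all-`NA` result with
#' `degenerate = TRUE`).
#'
#' @param tab 2x2 numeric matrix of counts.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List: `statistic`, `df`, `p_value`, `odds_ratio`,
#'   `haldane`, `degenerate`.
#' @export
association_test <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be a 2x2 matrix")
  if (any(tab < 0) || any(!is.finite(tab))) stop("counts must be >= 0")
  if (sum(tab) == 0) stop("table is empty")
  haldane <- any(tab == 0)
  or_tab <- if (haldane) tab + 0.5 else tab
  or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
                odds_ratio = or, haldane = haldane, degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, odds_ratio = or, haldane = haldane,
       degenerate = FALSE)
}

#' Characterize newly formed loops
#'
#' New loops are typed Bait-Bait / Bait-Nonbait against the WT bait set
#' (the capture design is fixed, so baits are WT baits). New Nonbait
#' anchors are anchors of new loops that are neither WT baits nor
#' anchors of any WT loop; each is reported with the bait class of its
#' partner anchor, feeding the occupancy-enrichment analysis.
#'
#' @param new_loops New loop data.frame (from [match_loops()]).
#' @param wt_baits WT bait table.
#' @param wt_anchor_ids Fragment ids anchoring any WT loop.
#' @return List: `baitness` summary data.frame, `new_nonbait_anchors`
#'   data.frame (`fragment_id`, `partner_class`).
#' @export
characterize_new_loops <- function(new_loops, wt_baits, wt_anchor_ids) {
  in_bait <- function(x) x %in% wt_baits$fragment_id
  nb <- in_bait(new_loops$anchorA) + in_bait(new_loops$anchorB)
  baitness <- ifelse(nb == 2L, "BAIT_BAIT",
                     ifelse(nb == 1L, "BAIT_NONBAIT", "NONBAIT_NONBAIT"))
  tab <- table(factor(baitness,
                      levels = c("BAIT_BAIT", "BAIT_NONBAIT",
                                 "NONBAIT_NONBAIT")))
  summary <- data.frame(baitness = names(tab), n = as.integer(tab),
                        proportion = as.integer(tab) / max(1L, nrow(new_loops)),
                        stringsAsFactors = FALSE)
  seen <- unique(c(wt_baits$fragment_id, wt_anchor_ids))
  rows <- list()
  for (i in seq_len(nrow(new_loops))) {
    pair <- c(new_loops$anchorA[i], new_loops$anchorB[i])
    fresh <- !pair %in% seen
    for (j in which(fresh)) {
      partner <- pair[-j]
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = pair[j],
        partner_class = if (in_bait(partner))
          wt_baits$bait_class[match(partner, wt_baits$fragment_id)]
        else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  nna <- if (length(rows) > 0L) unique(do.call(rbind, rows)) else
    data.frame(fragment_id = numeric(0), partner_class = character(0))
  rownames(nna) <- NULL
  list(baitness = summary, new_nonbait_anchors = nna)
}

#' Venn counts of named sets
#'
#' Counts elements by exact membership pattern across the supplied
#' sets (the usual Venn-diagram region counts).
#'
#' @param sets Named list of vectors.
#' @return Data.frame `pattern` (e.g. `"A&B"`), `n`.
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  all_el <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_el %in% s,
                   logical(length(all_el)))
  if (length(all_el) == 1L) member <- matrix(member, nrow = 1L)
  pattern <- apply(member, 1L, function(r) paste(names(sets)[r],
                                                 collapse = "&"))
  tab <- table(pattern)
  data.frame(pattern = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
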