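# Linking loop classes to transcription: grouping of bait regions
# into PcG hub / Pure / Nonloop (crossed with the bait subtype),
# gene-to-region assignment, expression-bin proportions, and the
# fraction of up-regulated genes per loop-fate cell.

LOOP_STATUS <- c("PCG_HUB", "PURE", "NONLOOP")

#' Group bait regions by loop participation
#'
#' Each bait fragment falls in exactly one of six groups: loop status
#' (anchors at least one PcG-hub loop > anchors only Pure loops > is
#' no loop's anchor) crossed with its bait subtype (only-H2Aub vs
#' H2Aub/H3K27me3).
#'
#' @param baits Bait table.
#' @param loops Classified loop table (needs `final_class`).
#' @return Data.frame `fragment_id`, `bait_class`, `loop_status`.
#' @export
group_bait_regions <- function(baits, loops) {
  if (!"final_class" %in% names(loops)) stop("loops need final_class")
  hub <- startsWith(loops$final_class, "PCGHUB")
  hub_anchors <- unique(c(loops$anchorA[hub], loops$anchorB[hub]))
  any_anchors <- unique(c(loops$anchorA, loops$anchorB))
  status <- ifelse(baits$fragment_id %in% hub_anchors, "PCG_HUB",
                   ifelse(baits$fragment_id %in% any_anchors, "PURE",
                          "NONLOOP"))
  data.frame(fragment_id = baits$fragment_id,
             bait_class = baits$bait_class,
             loop_status = status, stringsAsFactors = FALSE)
}

#' Assign genes to bait-region groups
#'
#' A gene joins a bait region when its gene body overlaps the region's
#' fragment by at least 1 bp. A gene overlapping regions of several
#' groups is assigned once, by precedence PcG hub > Pure > Nonloop and,
#' within a status, H2Aub/H3K27me3 before only-H2Aub (a fixed
#' tie-break so that the six groups stay disjoint at gene level).
#'
#' @param bait_groups Output of [group_bait_regions()].
#' @param fragments Fragment map.
#' @param genes Gene interval data.frame with `gene_id`.
#' @return Data.frame `gene_id`, `fragment_id`, `bait_class`,
#'   `loop_status`.
#' @export
assign_genes_to_regions <- function(bait_groups, fragments, genes) {
  check_regions(genes, "genes")
  frags <- fragments_by_id(fragments, bait_groups$fragment_id)
  ov <- find_region_overlaps(genes, frags)
  if (nrow(ov) == 0L) {
    return(data.frame(gene_id = character(0), fragment_id = numeric(0),
                      bait_class = character(0), loop_status = character(0)))
  }
  cand <- data.frame(
    gene_id = genes$gene_id[ov$query],
    fragment_id = bait_groups$fragment_id[ov$subject],
    bait_class = bait_groups$bait_class[ov$subject],
    loop_status = bait_groups$loop_status[ov$subject],
    stringsAsFactors = FALSE)
  rank_status <- match(cand$loop_status, LOOP_STATUS)
  rank_class <- match(cand$bait_class,
                      c("H2AUB_H3K27ME3", "ONLY_H2AUB"))
  ord <- order(cand$gene_id, rank_status, rank_class, cand$fragment_id)
  cand <- cand[ord, , drop = FALSE]
  out <- cand[!duplicated(cand$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expression-bin proportions per region group
#'
#' Bins gene expression into a zero bin plus bins delimited by
#' `bin_edges` (default: quartiles of the nonzero expression values of
#' the assigned genes) and reports per-group proportions, which sum to
#' 1 within each group. Empty groups are omitted with a warning.
#'
#' @param assignments Gene-group assignment
#'   ([assign_genes_to_regions()]).
#' @param expression Data.frame `gene_id`, `expression`.
#' @param bin_edges Optional increasing numeric vector of interior bin
#'   edges for the nonzero values.
#' @return Data.frame `loop_status`, `bait_class`, `bin`, `n`,
#'   `proportion`.
#' @export
expression_proportions <- function(assignments, expression,
                                   bin_edges = NULL) {
  x <- merge(assignments, expression[, c("gene_id", "expression")],
             by = "gene_id")
  if (nrow(x) == 0L) stop("no assigned gene has an expression value")
  nz <- x$expression[x$expression > 0]
  if (is.null(bin_edges)) {
    bin_edges <- unique(as.numeric(stats::quantile(nz, c(0.25, 0.5, 0.75))))
  }
  edges <- c(0, bin_edges, Inf)
  labels <- c("zero", paste0("bin", seq_len(length(edges) - 1L)))
  bin <- ifelse(x$expression == 0, "zero",
                labels[-1L][findInterval(x$expression, edges,
                                         left.open = TRUE)])
  x$bin <- factor(bin, levels = labels)
  x$group <- paste(x$loop_status, x$bait_class, sep = ":")
  rows <- list()
  for (g in unique(x$group)) {
    sub <- x[x$group == g, , drop = FALSE]
    tab <- table(sub$bin)
    rows[[g]] <- data.frame(
      loop_status = sub$loop_status[1L], bait_class = sub$bait_class[1L],
      bin = names(tab), n = as.integer(tab),
      proportion = as.integer(tab) / nrow(sub), stringsAsFactors = FALSE)
  }
  empty <- setdiff(as.vector(outer(LOOP_STATUS,
                                   c("ONLY_H2AUB", "H2AUB_H3K27ME3"),
                                   paste, sep = ":")),
                   unique(x$group))
  if (length(empty) > 0L) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes at the bait anchors of each loop-fate cell
#'
#' Collects, for every fate cell (Ll/Hl, Ll/Hm, Lm/Hl, Lm/Hm), the
#' genes whose bodies overlap a bait anchor of a loop in that cell. A
#' gene can appear in several cells (it is counted within each cell it
#' touches).
#'
#' @param loops WT loops with `loop_fate` and `hm_fate`.
#' @param baits Bait table.
#' @param fragments Fragment map.
#' @param genes Gene interval data.frame with `gene_id`.
#' @return Data.frame `cell`, `gene_id` (unique pairs).
#' @export
genes_at_fate_anchors <- function(loops, baits, fragments, genes) {
  if (!all(c("loop_fate", "hm_fate") %in% names(loops))) {
    stop("loops need loop_fate and hm_fate")
  }
  cell <- paste0(loops$loop_fate, "/", loops$hm_fate)
  rows <- list()
  for (cl in FATE_CELLS) {
    sub <- loops[cell == cl, , drop = FALSE]
    ids <- unique(c(sub$anchorA, sub$anchorB))
    ids <- ids[ids %in% baits$fragment_id]
    if (length(ids) == 0L) next
    frags <- fragments_by_id(fragments, ids)
    ov <- find_region_overlaps(genes, frags)
    if (nrow(ov) == 0L) next
    rows[[cl]] <- data.frame(cell = cl,
                             gene_id = unique(genes$gene_id[ov$query]),
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(cell = character(0), gene_id = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of up-regulated genes per loop-fate cell
#'
#' For each fate cell, the fraction of its anchor genes labeled `up`
#' among anchor genes carrying any differential-expression label.
#' Cells with no labeled genes report `NA`. Gene counts are returned
#' alongside the fractions.
#'
#' @param cell_genes Data.frame `cell`, `gene_id`
#'   ([genes_at_fate_anchors()]).
#' @param de_labels Data.frame `gene_id`, `de_label` (supplied labels;
#'   this package never fits differential expression).
#' @return Data.frame `cell`, `n_genes`, `n_up`, `fraction_up`.
#' @export
upregulated_fraction_by_fate <- function(cell_genes, de_labels) {
  x <- merge(cell_genes, de_labels[, c("gene_id", "de_label")],
             by = "gene_id")
  rows <- lapply(FATE_CELLS, function(cl) {
    sub <- x[x$cell == cl, , drop = FALSE]
    n <- nrow(sub)
    nup <- sum(sub$de_label == "up")
    data.frame(cell = cl, n_genes = n, n_up = nup,
               fraction_up = if (n > 0L) nup / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
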