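# Independent oracles and small fixture builders used across the test
# suite. Oracles are deliberately naive (linear scans, all-pairs
# loops) and share no code with the implementation they check.

# Naive left-to-right scan digestion: cut 5' of each site occurrence.
oracle_digest <- function(seq, site = "GATC") {
  seq <- toupper(seq)
  hits <- gregexpr(site, seq, fixed = TRUE)[[1L]]
  cuts <- if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
  bounds <- sort(unique(c(0L, cuts, nchar(seq))))
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

# All-pairs interval overlap oracle.
oracle_overlap_pairs <- function(a, b, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      w <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (w >= min_overlap) {
        out[[length(out) + 1L]] <- data.frame(query = i, subject = j,
                                              overlap_bp = w)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = numeric(0)))
  }
  do.call(rbind, out)
}

# Brute-force five-way loop classification: per-loop baitness, PcG
# class from the anchor bait classes, hub membership by materializing
# the Both-loop anchor set and testing every loop against it.
oracle_classify <- function(anchorA, anchorB, bait_class_by_id) {
  cls <- function(id) {
    v <- bait_class_by_id[as.character(id)]
    ifelse(is.na(v), "NONBAIT", v)
  }
  n <- length(anchorA)
  ca <- cls(anchorA); cb <- cls(anchorB)
  keep <- !(ca == "NONBAIT" & cb == "NONBAIT")
  ca <- ca[keep]; cb <- cb[keep]
  a <- anchorA[keep]; b <- anchorB[keep]
  baitness <- ifelse(ca != "NONBAIT" & cb != "NONBAIT",
                     "BAIT_BAIT", "BAIT_NONBAIT")
  pcg <- character(length(a))
  for (i in seq_along(a)) {
    classes <- c(ca[i], cb[i])
    has_only <- "ONLY_H2AUB" %in% classes
    has_k27 <- "H2AUB_H3K27ME3" %in% classes
    pcg[i] <- if (has_only && has_k27) "BOTH"
    else if (has_k27) "H2AUB_H3K27ME3" else "ONLY_H2AUB"
  }
  seed <- unique(c(a[pcg == "BOTH"], b[pcg == "BOTH"]))
  hub <- logical(length(a))
  for (i in seq_along(a)) {
    hub[i] <- pcg[i] == "BOTH" || a[i] %in% seed || b[i] %in% seed
  }
  final <- ifelse(pcg == "BOTH", "PCGHUB_BOTH",
                  paste0(ifelse(hub, "PCGHUB_", "PURE_"), pcg))
  data.frame(anchorA = a, anchorB = b, baitness = baitness,
             pcg_class = pcg, hub_member = hub, final_class = final,
             stringsAsFactors = FALSE)
}

# Textbook Holm step-down adjustment.
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1L) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Per-base average signal over a region (brute force).
oracle_mean_occupancy <- function(track, chrom, start, end) {
  v <- numeric(end - start)
  sub <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    lo <- max(start, sub$start[i]); hi <- min(end, sub$end[i])
    if (hi > lo) v[(lo - start + 1L):(hi - start)] <- sub$value[i]
  }
  mean(v)
}

# Random loop-set instance: fragment ids 1..n_frag, a random bait
# subset with random subtypes, loops as distinct random pairs with at
# least the bait coverage left to chance.
random_loop_instance <- function(n_loops, n_frag = max(50L, n_loops),
                                 p_bait = 0.5, p_k27 = 0.4) {
  n_bait <- max(2L, rbinom(1L, n_frag, p_bait))
  bait_ids <- sample.int(n_frag, n_bait)
  bait_class <- ifelse(runif(n_bait) < p_k27, "H2AUB_H3K27ME3",
                       "ONLY_H2AUB")
  a <- sample.int(n_frag, n_loops, replace = TRUE)
  b <- sample.int(n_frag, n_loops, replace = TRUE)
  ok <- a != b
  a <- a[ok]; b <- b[ok]
  key <- paste(pmin(a, b), pmax(a, b))
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  list(anchorA = pmin(a, b), anchorB = pmax(a, b),
       baits = data.frame(fragment_id = bait_ids, bait_class = bait_class,
                          stringsAsFactors = FALSE))
}

# Random toy genome: a few chromosomes of random DNA (with occasional
# ambiguity codes) in which GATC occurs naturally.
random_toy_genome <- function(n_chroms = 3L, min_len = 2000L,
                              max_len = 9000L) {
  setNames(lapply(seq_len(n_chroms), function(i) {
    len <- sample(min_len:max_len, 1L)
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(0.245, 0.245, 0.245, 0.245, 0.02)),
          collapse = "")
  }), sprintf("c%d", seq_len(n_chroms)))
}

# Compact simulation configuration for module tests (same structure
# as the default study-scale configuration, smaller problem size).
# Named-list arguments override the compact defaults field by field.
small_sim_config <- function(seed = 1L, genome = list(), peaks = list(),
                             loops = list(), mutant = list(),
                             expression = list()) {
  sim_config(
    seed = seed,
    genome = modifyList(list(n_chroms = 2L, chrom_length = 300000L),
                        genome),
    peaks = modifyList(list(n_h2aub = 200L, n_k27_only = 40L), peaks),
    loops = modifyList(list(n_both = 60L, n_hub_only = 50L,
                            n_hub_k27 = 40L, n_pure_only = 10L,
                            n_pure_k27 = 6L, dist_meanlog = log(8000)),
                       loops),
    mutant = modifyList(list(n_new = 20L), mutant),
    expression = modifyList(list(n_extra_genes = 80L), expression))
}

# Classify a dataset's WT loops with the package pipeline functions.
classify_wt <- function(ds) {
  baits <- type_baits(map_regions_to_fragments(ds$peaks_h2aub, ds$fragments),
                      ds$fragments, ds$peaks_k27)
  classify_loops(ds$loops_wt, baits, ds$fragments, ds$peaks_k27)
}
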