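# Seeded generator of toy capture Hi-C datasets with planted ground
# truth: genome with controlled GATC spacing, H2Aub / H3K27me3 peak
# sets with a tunable co-marking fraction, loop sets with planted
# Both-loop-seeded hubs plus Pure loops and a Bait-Nonbait fraction,
# mutant loop / histone-modification co-loss with a planted
# association, newly formed mutant loops with fresh Nonbait anchors,
# and expression depressed by marking and loop membership. The
# generator is a pure function of its configuration (including the
# seed); truth tables are first-class outputs.

#' Build a simulation configuration
#'
#' Defaults describe a compact two-chromosome genome whose structure
#' echoes the statistical features of an H2Aub capture Hi-C study:
#' DpnII-sized fragments (geometric GATC gaps, mean 260 bp), a bait
#' set with a co-marking fraction, hub-dominated loop sets at a ~25 kb
#' median anchor distance with a 32% Bait-Nonbait fraction, strong
#' loop/HM co-loss in the mutant, and marking/looping-dependent
#' expression.
#'
#' @param seed Integer seed; the generator is deterministic given the
#'   full configuration.
#' @param genome,peaks,loops,mutant,expression Named lists overriding
#'   individual defaults (see the package vignette for the meaning and
#'   units of every field).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome = list(), peaks = list(),
                       loops = list(), mutant = list(),
                       expression = list()) {
  cfg <- list(
    seed = as.integer(seed),
    genome = modifyList(list(
      n_chroms = 2L,
      chrom_length = 1500000L,
      gatc_mean_gap = 260
    ), genome),
    peaks = modifyList(list(
      n_h2aub = 1000L,      # bait peak count
      f_both = 0.45,        # fraction of H2Aub peaks also K27-marked
      n_k27_only = 200L,    # K27 peaks outside baits
      min_frag_width = 150L,
      len_frac_range = c(0.6, 0.85)  # peak width as fraction of fragment
    ), peaks),
    loops = modifyList(list(
      n_both = 300L,
      n_hub_only = 250L,    # hub-attached only-H2Aub loops
      n_hub_k27 = 200L,     # hub-attached H2Aub/H3K27me3 loops
      n_pure_only = 40L,
      n_pure_k27 = 25L,
      bait_nonbait_fraction = 0.32,
      dist_meanlog = log(25000),
      dist_sdlog = 0.6
    ), loops),
    mutant = modifyList(list(
      p_hm_lost = 0.5,          # per bait fragment
      p_loss_given_hl = 0.8,    # P(loop lost | HM fate Hl)
      p_loss_given_hm = 0.2,
      hm_log2fc = -1,           # planted log2 change at lost peaks
      n_new = 80L,
      new_nonbait_fraction = 0.5
    ), mutant),
    expression = modifyList(list(
      base_meanlog = log(10), base_sdlog = 1, p_zero = 0.05,
      m_k27 = 0.4,   # multiplier for K27-marked regions
      m_loop = 0.6,  # multiplier for loop-anchor regions
      p_up = c("Ll/Hl" = 0.5, "Ll/Hm" = 0.3, "Lm/Hl" = 0.3,
               "Lm/Hm" = 0.05),
      p_up_background = 0.02, p_down = 0.02,
      n_extra_genes = 400L
    ), expression)
  )
  probs <- c(cfg$peaks$f_both, cfg$mutant$p_hm_lost,
             cfg$mutant$p_loss_given_hl, cfg$mutant$p_loss_given_hm,
             cfg$loops$bait_nonbait_fraction, cfg$mutant$new_nonbait_fraction,
             cfg$expression$p_up, cfg$expression$p_up_background,
             cfg$expression$p_down, cfg$expression$p_zero)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  counts <- c(cfg$peaks$n_h2aub, cfg$peaks$n_k27_only, cfg$loops$n_both,
              cfg$loops$n_hub_only, cfg$loops$n_hub_k27,
              cfg$loops$n_pure_only, cfg$loops$n_pure_k27,
              cfg$mutant$n_new)
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(cfg, class = "sim_config")
}

# Random DNA of length n with no GATC occurrence.
.scrubbed_dna <- function(n) {
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
             collapse = "")
  while (grepl("GATC", s, fixed = TRUE)) {
    s <- gsub("GATC", "AATC", s, fixed = TRUE)
  }
  s
}

# One chromosome with GATC sites planted at geometric gaps; site
# placement is exact because fillers are scrubbed of accidental sites
# and a planted GATC cannot create an overlapping occurrence.
.sim_chrom <- function(len, mean_gap) {
  gaps <- stats::rgeom(ceiling(len / mean_gap * 1.6) + 20L,
                       1 / mean_gap) + 1L
  while (sum(gaps + 4L) < len) {
    gaps <- c(gaps, stats::rgeom(50L, 1 / mean_gap) + 1L)
  }
  pieces <- character(0)
  pos <- 0L
  for (g in gaps) {
    if (pos + g + 4L > len) break
    pieces <- c(pieces, .scrubbed_dna(g), "GATC")
    pos <- pos + g + 4L
  }
  if (pos < len) pieces <- c(pieces, .scrubbed_dna(len - pos))
  paste(pieces, collapse = "")
}

# Step-function track: baseline everywhere, baseline + boost over the
# given (disjoint) peak intervals. chrom_lengths names the chromosomes.
.build_track <- function(peaks, chrom_lengths, baseline = 1,
                         values = NULL) {
  rows <- list()
  for (cr in names(chrom_lengths)) {
    len <- chrom_lengths[[cr]]
    sub <- peaks[peaks$chrom == cr, , drop = FALSE]
    o <- order(sub$start)
    sub <- sub[o, , drop = FALSE]
    v <- if (is.null(values)) rep(baseline, nrow(sub)) else
      values[peaks$chrom == cr][o]
    pos <- 0
    for (i in seq_len(nrow(sub))) {
      if (sub$start[i] > pos) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cr, start = pos, end = sub$start[i], value = baseline)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cr, start = sub$start[i], end = sub$end[i], value = v[i])
      pos <- sub$end[i]
    }
    if (pos < len) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cr, start = pos, end = len, value = baseline)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# size-safe single draw (sample() would misread a length-1 pool)
.sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Generate a synthetic capture Hi-C dataset with planted truth
#'
#' @param config A [sim_config()].
#' @return A list with components `genome` (named character),
#'   `chrom_lengths`, `fragments`, `peaks_h2aub`, `peaks_k27`,
#'   `baits` (planted bait table), `loops_wt`, `loops_mut`, `tracks`
#'   (named list of bedGraph data.frames: `h2aub_wt`, `h2aub_mut`,
#'   `k27_wt`, `k27_mut`, `k27me1_wt`), `genes`, `exons`,
#'   `expression`, `de_labels`, and `truth` (planted per-loop class,
#'   per-loop fate, per-fragment HM change, per-gene labels).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_dataset(config))
}

.simulate_dataset <- function(cfg) {
  gcf <- cfg$genome; pcf <- cfg$peaks; lcf <- cfg$loops
  mcf <- cfg$mutant; ecf <- cfg$expression

  ## genome and fragments ------------------------------------------------
  chroms <- sprintf("chr%d", seq_len(gcf$n_chroms))
  genome <- setNames(vapply(chroms, function(cr)
    .sim_chrom(gcf$chrom_length, gcf$gatc_mean_gap), ""), chroms)
  fragments <- digest_genome(genome)
  chrom_lengths <- attr(fragments, "chrom_lengths")

  ## peak placement -------------------------------------------------------
  elig <- fragments[fragments$end - fragments$start >= pcf$min_frag_width, ]
  n_pool_nonbait <- lcf$n_hub_only + lcf$n_hub_k27 + lcf$n_pure_only +
    lcf$n_pure_k27 + mcf$n_new
  need <- pcf$n_h2aub + pcf$n_k27_only + n_pool_nonbait
  if (need > nrow(elig)) {
    stop("infeasible geometry: need ", need, " eligible fragments, have ",
         nrow(elig))
  }
  take <- sample(nrow(elig))  # random eligible fragment order
  grab <- function(n) {
    ids <- elig$fragment_id[take[seq_len(n)]]
    take <<- take[-seq_len(n)]
    ids
  }
  bait_ids <- grab(pcf$n_h2aub)
  n_both_baits <- round(pcf$f_both * pcf$n_h2aub)
  both_bait_ids <- bait_ids[seq_len(n_both_baits)]
  only_bait_ids <- setdiff(bait_ids, both_bait_ids)
  k27_only_ids <- grab(pcf$n_k27_only)
  nonbait_pool <- grab(n_pool_nonbait)  # peak-free partner/new fragments

  centered_peak <- function(ids) {
    fr <- fragments_by_id(fragments, ids)
    w <- fr$end - fr$start
    pw <- pmax(50, round(w * stats::runif(length(ids),
                                          pcf$len_frac_range[1],
                                          pcf$len_frac_range[2])))
    mid <- floor((fr$start + fr$end) / 2)
    data.frame(chrom = fr$chrom, start = pmax(fr$start, mid - floor(pw / 2)),
               end = pmin(fr$end, mid + ceiling(pw / 2)),
               fragment_id = ids, stringsAsFactors = FALSE)
  }
  peaks_h2aub <- centered_peak(bait_ids)
  peaks_k27 <- centered_peak(c(both_bait_ids, k27_only_ids))
  baits <- data.frame(
    fragment_id = sort(bait_ids),
    bait_class = ifelse(sort(bait_ids) %in% both_bait_ids,
                        "H2AUB_H3K27ME3", "ONLY_H2AUB"),
    stringsAsFactors = FALSE)

  ## loop planting --------------------------------------------------------
  frag_mid <- setNames(region_midpoints(fragments), fragments$fragment_id)
  frag_chrom <- setNames(fragments$chrom, fragments$fragment_id)
  used <- new.env(parent = emptyenv())
  pair_key <- function(a, b) paste0(min(a, b), ":", max(a, b))
  pick_partner <- function(anchor, pool) {
    cr <- frag_chrom[[as.character(anchor)]]
    cand <- pool[frag_chrom[as.character(pool)] == cr & pool != anchor]
    if (length(cand) == 0L) return(NA_real_)
    d <- stats::rlnorm(1, lcf$dist_meanlog, lcf$dist_sdlog)
    err <- abs(abs(frag_mid[as.character(cand)] -
                     frag_mid[[as.character(anchor)]]) - d)
    for (j in order(err)) {
      key <- pair_key(anchor, cand[j])
      if (!exists(key, envir = used, inherits = FALSE)) return(cand[j])
    }
    NA_real_
  }

  # Both-dependent loop types need both bait subtypes; degrade their
  # counts to zero (with a message) when co-marking is absent
  if (length(both_bait_ids) == 0L || lcf$n_both == 0L) {
    if (lcf$n_hub_only + lcf$n_hub_k27 > 0L) {
      message("no Both-loops plantable; hub-attached loop counts set to 0")
    }
    lcf$n_both <- if (length(both_bait_ids) == 0L) 0L else lcf$n_both
    lcf$n_hub_only <- 0L
    lcf$n_hub_k27 <- 0L
  }
  if (length(both_bait_ids) == 0L && lcf$n_pure_k27 > 0L) {
    message("no H2Aub/H3K27me3 baits; Pure H2Aub/H3K27me3 loop count set to 0")
    lcf$n_pure_k27 <- 0L
  }

  # pools: pure loops draw from reserves disjoint from hub seeds so
  # that planted Pure loops can never share an anchor with a Both-loop
  n_pure_only_pool <- min(2L * lcf$n_pure_only, length(only_bait_ids) %/% 3L)
  n_pure_k27_pool <- min(2L * lcf$n_pure_k27, length(both_bait_ids) %/% 3L)
  pure_only_pool <- only_bait_ids[seq_len(n_pure_only_pool)]
  seed_only_pool <- setdiff(only_bait_ids, pure_only_pool)
  pure_k27_pool <- both_bait_ids[seq_len(n_pure_k27_pool)]
  seed_both_pool <- setdiff(both_bait_ids, pure_k27_pool)
  if (lcf$n_both > 0L &&
      (length(seed_only_pool) == 0L || length(seed_both_pool) == 0L)) {
    stop("infeasible: Both-loops requested but a bait pool is empty")
  }

  plant <- list()
  add_loop <- function(a, b, pcg, hub, baitness) {
    key <- pair_key(a, b)
    assign(key, TRUE, envir = used)
    plant[[length(plant) + 1L]] <<- data.frame(
      anchorA = min(a, b), anchorB = max(a, b), pcg_class = pcg,
      hub_member = hub, baitness = baitness, stringsAsFactors = FALSE)
  }

  # Both-loops (hub seeds)
  n_planted_both <- 0L
  guard <- 0L
  while (n_planted_both < lcf$n_both && guard < 50L * lcf$n_both) {
    guard <- guard + 1L
    a <- .sample1(seed_only_pool)
    b <- pick_partner(a, seed_both_pool)
    if (is.na(b)) next
    add_loop(a, b, "BOTH", TRUE, "BAIT_BAIT")
    n_planted_both <- n_planted_both + 1L
  }
  if (n_planted_both < lcf$n_both) {
    stop("infeasible: could not place the requested Both-loops")
  }
  seed_anchors <- if (length(plant) > 0L) {
    both_df <- do.call(rbind, plant)
    unique(c(both_df$anchorA, both_df$anchorB))
  } else numeric(0)
  seed_only_anchors <- intersect(seed_anchors, only_bait_ids)
  seed_both_anchors <- intersect(seed_anchors, both_bait_ids)

  plant_attached <- function(n, attach_pool, partner_pool, pcg) {
    planted <- 0L; guard <- 0L
    while (planted < n && guard < 60L * max(1L, n)) {
      guard <- guard + 1L
      a <- .sample1(attach_pool)
      nonbait <- stats::runif(1) < lcf$bait_nonbait_fraction
      pool <- if (nonbait) nonbait_pool else partner_pool
      b <- pick_partner(a, pool)
      if (is.na(b)) next
      if (nonbait) {
        # consume the fragment so each Nonbait anchor is fresh
        nonbait_pool <<- setdiff(nonbait_pool, b)
      }
      add_loop(a, b, pcg, TRUE, if (nonbait) "BAIT_NONBAIT" else "BAIT_BAIT")
      planted <- planted + 1L
    }
    if (planted < n) stop("infeasible: could not place hub-attached loops")
  }
  plant_attached(lcf$n_hub_only, seed_only_anchors, seed_only_pool,
                 "ONLY_H2AUB")
  plant_attached(lcf$n_hub_k27, seed_both_anchors, seed_both_pool,
                 "H2AUB_H3K27ME3")

  plant_pure <- function(n, pool, pcg) {
    planted <- 0L; guard <- 0L
    while (planted < n && guard < 60L * max(1L, n)) {
      guard <- guard + 1L
      a <- .sample1(pool)
      nonbait <- stats::runif(1) < lcf$bait_nonbait_fraction
      pp <- if (nonbait) nonbait_pool else pool
      b <- pick_partner(a, pp)
      if (is.na(b)) next
      if (nonbait) nonbait_pool <<- setdiff(nonbait_pool, b)
      add_loop(a, b, pcg, FALSE, if (nonbait) "BAIT_NONBAIT" else "BAIT_BAIT")
      planted <- planted + 1L
    }
    if (planted < n) stop("infeasible: could not place Pure loops")
  }
  if (lcf$n_pure_only > 0L) plant_pure(lcf$n_pure_only, pure_only_pool,
                                       "ONLY_H2AUB")
  if (lcf$n_pure_k27 > 0L) plant_pure(lcf$n_pure_k27, pure_k27_pool,
                                      "H2AUB_H3K27ME3")

  planted <- do.call(rbind, plant)
  loops_wt <- make_loops(planted$anchorA, planted$anchorB,
                         score = round(stats::runif(nrow(planted), 5, 30), 2),
                         fragments = fragments)
  truth_class <- data.frame(
    loop_id = loops_wt$loop_id,
    baitness = planted$baitness,
    pcg_class = planted$pcg_class,
    hub_member = planted$hub_member,
    final_class = ifelse(planted$pcg_class == "BOTH", "PCGHUB_BOTH",
                         paste0(ifelse(planted$hub_member, "PCGHUB_", "PURE_"),
                                planted$pcg_class)),
    stringsAsFactors = FALSE)

  ## mutant: HM loss at bait fragments, loop fates ------------------------
  hm_lost <- stats::rbinom(nrow(baits), 1L, mcf$p_hm_lost) == 1L
  truth_hm <- do.call(rbind, lapply(seq_len(nrow(baits)), function(i) {
    marks <- if (baits$bait_class[i] == "H2AUB_H3K27ME3")
      c("H2Aub", "H3K27me3") else "H2Aub"
    data.frame(fragment_id = baits$fragment_id[i], mark = marks,
               log2fc = ifelse(hm_lost[i], mcf$hm_log2fc, 0),
               decreased = hm_lost[i], stringsAsFactors = FALSE)
  }))
  lost_ids <- baits$fragment_id[hm_lost]

  # HM fate per WT loop, by the anchor rule on planted fragment losses
  loop_hm_fate <- vapply(seq_len(nrow(loops_wt)), function(i) {
    ids <- c(loops_wt$anchorA[i], loops_wt$anchorB[i])
    ids <- ids[ids %in% baits$fragment_id]
    if (any(ids %in% lost_ids)) "Hl" else "Hm"
  }, "")
  p_loss <- ifelse(loop_hm_fate == "Hl", mcf$p_loss_given_hl,
                   mcf$p_loss_given_hm)
  loop_lost <- stats::rbinom(nrow(loops_wt), 1L, p_loss) == 1L
  truth_fate <- data.frame(
    loop_id = loops_wt$loop_id,
    loop_fate = ifelse(loop_lost, "Ll", "Lm"),
    hm_fate = loop_hm_fate,
    cell = paste0(ifelse(loop_lost, "Ll", "Lm"), "/", loop_hm_fate),
    stringsAsFactors = FALSE)

  ## new mutant loops ------------------------------------------------------
  new_anchor_pool <- nonbait_pool
  new_rows <- list()
  guard <- 0L
  while (length(new_rows) < mcf$n_new && guard < 80L * max(1L, mcf$n_new)) {
    guard <- guard + 1L
    a <- .sample1(baits$fragment_id)
    fresh <- stats::runif(1) < mcf$new_nonbait_fraction
    pool <- if (fresh) new_anchor_pool else baits$fragment_id
    b <- pick_partner(a, pool)
    if (is.na(b)) next
    if (fresh) new_anchor_pool <- setdiff(new_anchor_pool, b)
    assign(pair_key(a, b), TRUE, envir = used)
    new_rows[[length(new_rows) + 1L]] <- c(min(a, b), max(a, b))
  }
  loops_new <- if (length(new_rows) > 0L) {
    new_mat <- do.call(rbind, new_rows)
    make_loops(new_mat[, 1], new_mat[, 2],
               score = round(stats::runif(nrow(new_mat), 5, 30), 2),
               fragments = fragments)
  } else {
    loops_wt[0L, , drop = FALSE]
  }
  kept <- loops_wt[!loop_lost, , drop = FALSE]
  loops_mut <- rbind(kept, loops_new)
  rownames(loops_mut) <- NULL
  attr(loops_mut, "fragment_map") <- fragment_map_signature(fragments)
  new_nonbait_ids <- setdiff(unique(c(loops_new$anchorA, loops_new$anchorB)),
                             c(baits$fragment_id, loops_wt$anchorA,
                               loops_wt$anchorB))

  ## signal tracks ---------------------------------------------------------
  boost <- 7
  fc <- 2^mcf$hm_log2fc
  mk_tracks <- function(peaks) {
    lost <- peaks$fragment_id %in% lost_ids
    wt_v <- rep(1 + boost, nrow(peaks))
    mut_v <- ifelse(lost, 1 + boost * fc, 1 + boost)
    list(wt = .build_track(peaks, chrom_lengths, baseline = 1, values = wt_v),
         mut = .build_track(peaks, chrom_lengths, baseline = 1,
                            values = mut_v))
  }
  tr_h2aub <- mk_tracks(peaks_h2aub)
  tr_k27 <- mk_tracks(peaks_k27)
  # heterochromatin-like mark concentrated at the fragments recruited
  # as fresh Nonbait anchors of new mutant loops
  k27me1_regions <- fragments_by_id(fragments, new_nonbait_ids)
  tr_k27me1 <- .build_track(k27me1_regions, chrom_lengths, baseline = 1,
                            values = rep(4, nrow(k27me1_regions)))

  ## genes and expression ---------------------------------------------------
  extra_ids <- grab(min(ecf$n_extra_genes, length(take)))
  gene_frag_ids <- c(sort(bait_ids), sort(extra_ids))
  gf <- fragments_by_id(fragments, gene_frag_ids)
  pad <- pmax(5, floor((gf$end - gf$start) * 0.1))
  genes <- data.frame(
    gene_id = sprintf("GENE%05d", seq_along(gene_frag_ids)),
    chrom = gf$chrom, start = gf$start + pad, end = gf$end - pad,
    strand = sample(c("+", "-"), length(gene_frag_ids), replace = TRUE),
    fragment_id = gene_frag_ids, stringsAsFactors = FALSE)
  genes <- genes[genes$end - genes$start >= 60, , drop = FALSE]
  exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    w <- genes$end[i] - genes$start[i]
    if (w < 200) {
      data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                 start = genes$start[i], end = genes$end[i],
                 stringsAsFactors = FALSE)
    } else {
      cut1 <- genes$start[i] + floor(w * 0.4)
      cut2 <- genes$start[i] + floor(w * 0.6)
      data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                 start = c(genes$start[i], cut2),
                 end = c(cut1, genes$end[i]), stringsAsFactors = FALSE)
    }
  }))
  anchor_ids <- unique(c(loops_wt$anchorA, loops_wt$anchorB))
  k27_frag_ids <- c(both_bait_ids, k27_only_ids)
  base_expr <- stats::rlnorm(nrow(genes), ecf$base_meanlog, ecf$base_sdlog)
  mult <- ifelse(genes$fragment_id %in% k27_frag_ids, ecf$m_k27, 1) *
    ifelse(genes$fragment_id %in% anchor_ids, ecf$m_loop, 1)
  expr <- base_expr * mult
  expr[stats::runif(nrow(genes)) < ecf$p_zero] <- 0
  expression <- data.frame(gene_id = genes$gene_id,
                           expression = round(expr, 3),
                           stringsAsFactors = FALSE)

  # differential labels: genes at WT loop anchors inherit the riskiest
  # fate cell among their loops, which sets their up-probability
  cell_rank <- c("Ll/Hl" = 1, "Ll/Hm" = 2, "Lm/Hl" = 3, "Lm/Hm" = 4)
  frag_cells <- list()
  for (i in seq_len(nrow(loops_wt))) {
    for (id in c(loops_wt$anchorA[i], loops_wt$anchorB[i])) {
      k <- as.character(id)
      cl <- truth_fate$cell[i]
      if (is.null(frag_cells[[k]]) ||
          cell_rank[[cl]] < cell_rank[[frag_cells[[k]]]]) {
        frag_cells[[k]] <- cl
      }
    }
  }
  gene_cell <- vapply(as.character(genes$fragment_id), function(k) {
    frag_cells[[k]] %||% NA_character_
  }, "")
  p_up <- ifelse(is.na(gene_cell), ecf$p_up_background,
                 ecf$p_up[gene_cell])
  r <- stats::runif(nrow(genes))
  de <- ifelse(r < p_up, "up",
               ifelse(r < p_up + ecf$p_down, "down", "ns"))
  de_labels <- data.frame(gene_id = genes$gene_id, de_label = de,
                          stringsAsFactors = FALSE)
  truth_de <- data.frame(gene_id = genes$gene_id, cell = gene_cell,
                         de_label = de, stringsAsFactors = FALSE)

  list(
    config = cfg,
    genome = genome,
    chrom_lengths = chrom_lengths,
    fragments = fragments,
    peaks_h2aub = peaks_h2aub[, c("chrom", "start", "end")],
    peaks_k27 = peaks_k27[, c("chrom", "start", "end")],
    baits = baits,
    loops_wt = loops_wt,
    loops_mut = loops_mut,
    tracks = list(h2aub_wt = tr_h2aub$wt, h2aub_mut = tr_h2aub$mut,
                  k27_wt = tr_k27$wt, k27_mut = tr_k27$mut,
                  k27me1_wt = tr_k27me1),
    genes = genes,
    exons = exons,
    expression = expression,
    de_labels = de_labels,
    truth = list(baits = baits, loop_class = truth_class,
                 loop_fate = truth_fate, hm_change = truth_hm,
                 new_loops = loops_new$loop_id,
                 new_nonbait_anchors = new_nonbait_ids,
                 de = truth_de)
  )
}

#' Write a simulated dataset to disk in standard formats
#'
#' Emits FASTA (genome), BED (peaks), bedGraph (tracks), BEDPE-like
#' loop tables, GFF3 (genes/exons), TSV (expression, DE labels) and
#' the planted truth tables.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  loops_to_table <- function(loops, fragments) {
    fa <- fragments_by_id(fragments, loops$anchorA)
    fb <- fragments_by_id(fragments, loops$anchorB)
    data.frame(chromA = fa$chrom, startA = fa$start, endA = fa$end,
               chromB = fb$chrom, startB = fb$start, endB = fb$end,
               score = loops$score, stringsAsFactors = FALSE)
  }
  write_fasta(dataset$genome, p("genome.fa"))
  write_bed(dataset$peaks_h2aub, p("h2aub_peaks.bed"))
  write_bed(dataset$peaks_k27, p("k27_peaks.bed"))
  write_loop_table(loops_to_table(dataset$loops_wt, dataset$fragments),
                   p("loops_wt.tsv"))
  write_loop_table(loops_to_table(dataset$loops_mut, dataset$fragments),
                   p("loops_mut.tsv"))
  for (nm in names(dataset$tracks)) {
    write_bedgraph(dataset$tracks[[nm]], p(sprintf("%s.bedgraph", nm)))
  }
  write_gff3(dataset$genes, dataset$exons, p("genes.gff3"))
  write_tsv(dataset$expression, p("expression.tsv"))
  write_tsv(dataset$de_labels, p("de_labels.tsv"))
  write_tsv(dataset$truth$loop_class, p("truth_loop_class.tsv"))
  write_tsv(dataset$truth$loop_fate, p("truth_loop_fate.tsv"))
  write_tsv(dataset$truth$hm_change, p("truth_hm_change.tsv"))
  write_tsv(dataset$truth$de, p("truth_de.tsv"))
  write_tsv(dataset$baits, p("truth_baits.tsv"))
  files <- list.files(dir, full.names = TRUE)
  invisible(setNames(files, basename(files)))
}

#' Compare pipeline output against planted truth
#'
#' Joins truth and predicted labels on their shared identifier and
#' returns the confusion table plus per-class precision and recall.
#' Identifiers present in only one of the two tables are an error.
#'
#' @param truth Data.frame with an id column and a label column.
#' @param predicted Data.frame with the same id column and a label
#'   column.
#' @param id,truth_col,pred_col Column names.
#' @return List: `confusion` (table, truth in rows), `per_class`
#'   data.frame with precision/recall, `accuracy`.
#' @export
planted_truth_compare <- function(truth, predicted, id = "loop_id",
                                  truth_col, pred_col) {
  if (!setequal(truth[[id]], predicted[[id]])) {
    stop("identifier mismatch between truth and prediction")
  }
  m <- match(truth[[id]], predicted[[id]])
  t_lab <- truth[[truth_col]]
  p_lab <- predicted[[pred_col]][m]
  lev <- sort(unique(c(t_lab, p_lab)))
  conf <- table(truth = factor(t_lab, lev), predicted = factor(p_lab, lev))
  per_class <- data.frame(
    class = lev,
    precision = vapply(lev, function(l) {
      d <- sum(conf[, l]); if (d == 0) NA_real_ else conf[l, l] / d
    }, numeric(1)),
    recall = vapply(lev, function(l) {
      d <- sum(conf[l, ]); if (d == 0) NA_real_ else conf[l, l] / d
    }, numeric(1)),
    stringsAsFactors = FALSE)
  list(confusion = conf, per_class = per_class,
       accuracy = sum(diag(conf)) / sum(conf))
}

#' Simulate coupled loop and histone-modification fates
#'
#' Minimal generative model for the loop-loss / HM-loss association:
#' each loop loses its anchor modification with probability `p_hl`,
#' then disappears with probability `p_loss_given_hl` or
#' `p_loss_given_hm` depending on that state. The generative odds
#' ratio is `(p_loss_given_hl / (1 - p_loss_given_hl)) /
#' (p_loss_given_hm / (1 - p_loss_given_hm))`.
#'
#' @param n Number of loops.
#' @param p_loss_given_hl,p_loss_given_hm Conditional loss
#'   probabilities.
#' @param p_hl HM-loss prevalence.
#' @param seed Optional seed.
#' @return Data.frame `hm_fate`, `loop_fate` plus the 2x2 count matrix
#'   as attribute `table` (rows Ll/Lm, columns Hl/Hm).
#' @export
simulate_loop_fates <- function(n, p_loss_given_hl = 0.8,
                                p_loss_given_hm = 0.2, p_hl = 0.5,
                                seed = NULL) {
  draw <- function() {
    hl <- stats::rbinom(n, 1L, p_hl) == 1L
    lost <- stats::rbinom(n, 1L, ifelse(hl, p_loss_given_hl,
                                        p_loss_given_hm)) == 1L
    out <- data.frame(hm_fate = ifelse(hl, "Hl", "Hm"),
                      loop_fate = ifelse(lost, "Ll", "Lm"),
                      stringsAsFactors = FALSE)
    tab <- matrix(c(sum(lost & hl), sum(lost & !hl),
                    sum(!lost & hl), sum(!lost & !hl)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(loop_fate = c("Ll", "Lm"),
                                  hm_fate = c("Hl", "Hm")))
    attr(out, "table") <- tab
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
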