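# Single entry point chaining the analysis stages on a simulated or
# on-disk dataset, with a machine-readable run manifest.

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: (1) obtain data — either simulate a
#' dataset from `config$simulate` or load the files named in
#' `config$inputs`; (2) digest/bait mapping and bait typing;
#' (3) loop classification (WT and mutant); (4) WT-vs-mutant
#' comparison with HM fates and association test; (5) occupancy
#' enrichment at fresh Nonbait anchors of new loops; (6) expression
#' linkage. Missing input files are reported before any stage runs; a
#' stage failure stops the run with the partial manifest attached to
#' the error condition.
#'
#' @param config A list (or path to a YAML file) with either
#'   `simulate` (arguments for [sim_config()], e.g. `seed`) or
#'   `inputs` (paths: `genome`, `h2aub_peaks`, `k27_peaks`,
#'   `loops_wt`, `loops_mut`, `h2aub_wt`, `h2aub_mut`, `k27_wt`,
#'   `k27_mut`, `genes`, `expression`, `de_labels`, optional extra
#'   tracks under `tracks`).
#' @param out_dir Directory for result tables and the manifest.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("pcgloop_run")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  # pre-flight: every named input must exist before any stage runs
  input_files <- unlist(config$inputs, use.names = TRUE)
  if (is.null(input_files)) input_files <- character(0)
  missing <- input_files[!file.exists(input_files)]
  if (length(missing) > 0L) {
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", names(missing), missing), collapse = ", "))
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("config must provide either 'simulate' or 'inputs'")
  }

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "pcgloop", version = pcgloop_version(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(tools::md5sum(cfg_file)),
    input_checksums = as.list(if (length(input_files) > 0L)
      tools::md5sum(input_files) else character(0)),
    stages = list())
  stage <- function(name, counts, outputs = character(0)) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, counts = as.list(counts),
           outputs = as.list(outputs))
  }

  ## stage 1: data --------------------------------------------------------
  if (!is.null(config$simulate)) {
    ds <- simulate_dataset(do.call(sim_config, config$simulate))
    fragments <- ds$fragments
    h2aub_peaks <- ds$peaks_h2aub; k27_peaks <- ds$peaks_k27
    loops_wt_raw <- ds$loops_wt; loops_mut_raw <- ds$loops_mut
    tracks <- ds$tracks
    genes <- ds$genes; exons <- ds$exons
    expression <- ds$expression; de_labels <- ds$de_labels
    stage("data", c(n_fragments = nrow(fragments),
                    n_h2aub_peaks = nrow(h2aub_peaks),
                    n_k27_peaks = nrow(k27_peaks)))
  } else {
    inp <- config$inputs
    genome <- read_fasta(inp$genome)
    fragments <- digest_genome(genome)
    h2aub_peaks <- read_bed(inp$h2aub_peaks)
    k27_peaks <- read_bed(inp$k27_peaks)
    loops_wt_raw <- loops_from_regions(read_loop_table(inp$loops_wt),
                                       fragments)
    loops_mut_raw <- loops_from_regions(read_loop_table(inp$loops_mut),
                                        fragments)
    tracks <- list(h2aub_wt = read_bedgraph(inp$h2aub_wt),
                   h2aub_mut = read_bedgraph(inp$h2aub_mut),
                   k27_wt = read_bedgraph(inp$k27_wt),
                   k27_mut = read_bedgraph(inp$k27_mut))
    for (nm in names(config$inputs$tracks %||% list())) {
      tracks[[nm]] <- read_bedgraph(inp$tracks[[nm]])
    }
    gm <- read_gff_genes(inp$genes)
    genes <- gm$genes; exons <- gm$exons
    expression <- read_expression(inp$expression)
    de_labels <- read_de_labels(inp$de_labels)
    stage("data", c(n_fragments = nrow(fragments),
                    n_h2aub_peaks = nrow(h2aub_peaks),
                    n_k27_peaks = nrow(k27_peaks)))
  }

  ## stage 2: baits -------------------------------------------------------
  bait_ids <- map_regions_to_fragments(h2aub_peaks, fragments)
  baits <- type_baits(bait_ids, fragments, k27_peaks)
  stage("baits", c(n_baits = nrow(baits),
                   n_k27_baits = sum(baits$bait_class == "H2AUB_H3K27ME3")))

  ## stage 3: classification ----------------------------------------------
  loops_wt <- classify_loops(loops_wt_raw, baits, fragments, k27_peaks)
  loops_mut <- classify_loops(loops_mut_raw, baits, fragments, k27_peaks)
  class_file <- file.path(out_dir, "loops_wt_classified.tsv")
  write_loop_table(loops_wt, class_file)
  stage("classify",
        c(n_wt = nrow(loops_wt), n_mut = nrow(loops_mut),
          n_hub = sum(loops_wt$hub_member),
          n_both = sum(loops_wt$pcg_class == "BOTH")),
        class_file)

  ## stage 4: mutant comparison -------------------------------------------
  matched <- match_loops(loops_wt, loops_mut)
  loops_wt <- loop_fates(loops_wt, matched)
  hm <- rbind(
    hm_change(baits$fragment_id, fragments, tracks$h2aub_wt,
              tracks$h2aub_mut, "H2Aub"),
    hm_change(baits$fragment_id, fragments, tracks$k27_wt,
              tracks$k27_mut, "H3K27me3"))
  loops_wt <- hm_fate_at_anchors(loops_wt, hm, baits)
  cc <- cross_classify(loops_wt)
  assoc <- association_test(cc$counts)
  fate_file <- file.path(out_dir, "loops_wt_fates.tsv")
  write_loop_table(loops_wt, fate_file)
  newc <- characterize_new_loops(matched$new, baits,
                                 unique(c(loops_wt$anchorA,
                                          loops_wt$anchorB)))
  stage("compare",
        c(n_disappeared = nrow(matched$disappeared),
          n_maintained = nrow(matched$maintained),
          n_new = nrow(matched$new),
          chisq_stat = round(assoc$statistic, 4)),
        fate_file)

  ## stage 5: enrichment at new Nonbait anchors -----------------------------
  enrich <- NULL
  extra <- setdiff(names(tracks), c("h2aub_mut", "k27_mut"))
  if (nrow(newc$new_nonbait_anchors) > 1L && length(extra) > 0L) {
    targets <- fragments_by_id(fragments, newc$new_nonbait_anchors$fragment_id)
    genome_space <- chrom_space(fragments)
    enrich <- enrichment_test(tracks[extra], targets, genome_space,
                              seed = config$enrich_seed %||% 1L)
    write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))
    stage("enrich", c(n_targets = nrow(targets), n_marks = length(extra)),
          file.path(out_dir, "enrichment.tsv"))
  } else {
    stage("enrich", c(n_targets = 0L, n_marks = 0L))
  }

  ## stage 6: expression ----------------------------------------------------
  groups <- group_bait_regions(baits, loops_wt)
  assignments <- assign_genes_to_regions(groups, fragments, genes)
  props <- expression_proportions(assignments, expression)
  cell_genes <- genes_at_fate_anchors(loops_wt, baits, fragments, genes)
  upfrac <- upregulated_fraction_by_fate(cell_genes, de_labels)
  write_tsv(props, file.path(out_dir, "expression_proportions.tsv"))
  write_tsv(upfrac, file.path(out_dir, "upregulated_by_fate.tsv"))
  stage("expression",
        c(n_assigned_genes = nrow(assignments),
          n_fate_genes = nrow(cell_genes)),
        c(file.path(out_dir, "expression_proportions.tsv"),
          file.path(out_dir, "upregulated_by_fate.tsv")))

  manifest$results <- list(
    baits = baits, loops_wt = loops_wt, loops_mut = loops_mut,
    matched = matched, cross = cc, association = assoc,
    new_loops = newc, enrichment = enrich,
    expression_proportions = props, upregulated_by_fate = upfrac)
  json <- manifest
  json$results <- NULL
  jsonlite::write_json(json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Whole-chromosome genome space from a fragment map
#'
#' @param fragments Fragment map with `chrom_lengths`-style extent.
#' @return Interval data.frame covering each chromosome end to end.
#' @export
chrom_space <- function(fragments) {
  lens <- tapply(fragments$end, fragments$chrom, max)
  data.frame(chrom = names(lens), start = 0, end = as.numeric(lens),
             stringsAsFactors = FALSE)
}
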