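#' Design capture probes over peak regions
#'
#' Places probe-binding sites by the length-conditional rule used for
#' hybridization capture bait libraries: a region shorter than 300 bp
#' receives a single probe centered at its midpoint; a region of 300 to
#' 500 bp (inclusive) receives two probes centered at one-third and
#' two-thirds of its length; a region longer than 500 bp receives three
#' probes centered at one-quarter, one-half and three-quarters.
#' Fractional offsets are floored, so placement is deterministic. Each
#' probe interval is `[center - floor(P/2), center + ceiling(P/2))` for
#' probe length `P`; probes that would overhang the region are clipped
#' to the region boundary and flagged.
#'
#' @param peaks Interval data.frame of source regions; a `name` column,
#'   when present, is used as the region id.
#' @param probe_length Probe length in bp (default 100).
#' @return Probe data.frame with `region_id`, `index` (within region),
#'   `chrom`, `start`, `end`, `center`, `clipped`, and BED-ready
#'   `name` (`region_id:index`) and `score` (1 if clipped).
#' @examples
#' design_probes(regions("chr1", 1000, 1250)) # one probe at [1075,1175)
#' @export
design_probes <- function(peaks, probe_length = 100L) {
  check_regions(peaks, "peaks")
  if (probe_length < 1L) stop("probe_length must be >= 1")
  if (nrow(peaks) == 0L) {
    return(data.frame(region_id = character(0), index = integer(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), center = numeric(0),
                      clipped = logical(0), name = character(0),
                      score = integer(0)))
  }
  ids <- if ("name" %in% names(peaks)) as.character(peaks$name) else
    as.character(seq_len(nrow(peaks)))
  L <- peaks$end - peaks$start
  n_probes <- ifelse(L < 300, 1L, ifelse(L <= 500, 2L, 3L))
  rows <- rep(seq_len(nrow(peaks)), n_probes)
  index <- sequence(n_probes)
  frac_num <- list(`1` = 1, `2` = c(1, 2), `3` = c(1, 2, 3))
  frac_den <- c(`1` = 2, `2` = 3, `3` = 4)
  num <- unlist(frac_num[as.character(n_probes)], use.names = FALSE)
  den <- rep(frac_den[as.character(n_probes)], n_probes)
  center <- peaks$start[rows] + floor(L[rows] * num / den)
  half_lo <- floor(probe_length / 2)
  half_hi <- ceiling(probe_length / 2)
  start <- center - half_lo
  end <- center + half_hi
  clipped <- start < peaks$start[rows] | end > peaks$end[rows]
  start <- pmax(start, peaks$start[rows])
  end <- pmin(end, peaks$end[rows])
  data.frame(region_id = ids[rows], index = index,
             chrom = as.character(peaks$chrom)[rows],
             start = start, end = end, center = center,
             clipped = clipped,
             name = paste0(ids[rows], ":", index),
             score = as.integer(clipped),
             stringsAsFactors = FALSE)
}

#' Extract probe sequences from a genome
#'
#' @param probes Probe data.frame from [design_probes()].
#' @param genome Named character vector of chromosome sequences.
#' @return Named character vector of probe sequences.
#' @export
probe_sequences <- function(probes, genome) {
  miss <- setdiff(unique(probes$chrom), names(genome))
  if (length(miss) > 0L) stop("chromosome absent from genome: ",
                              paste(miss, collapse = ", "))
  setNames(substring(toupper(genome[probes$chrom]),
                     probes$start + 1L, probes$end),
           probes$name)
}

#' Count probes per gene
#'
#' A probe counts toward every gene whose footprint (gene body plus
#' upstream promoter window) it overlaps by at least 1 bp, so a probe
#' spanning two adjacent genes is counted for both. Genes with no
#' probes are reported with count 0.
#'
#' @param probes Probe data.frame.
#' @param genes Gene interval data.frame with `gene_id` and `strand`.
#' @param promoter_width Upstream promoter window in bp (default 1000).
#' @return Data.frame `gene_id`, `n_probes`.
#' @export
probes_per_gene <- function(probes, genes, promoter_width = 1000L) {
  check_regions(genes, "genes")
  if (!"gene_id" %in% names(genes)) stop("genes must carry gene_id")
  minus <- genes$strand == "-"
  span <- data.frame(chrom = genes$chrom,
                     start = ifelse(minus, genes$start,
                                    pmax(0, genes$start - promoter_width)),
                     end = ifelse(minus, genes$end + promoter_width,
                                  genes$end),
                     stringsAsFactors = FALSE)
  counts <- integer(nrow(genes))
  if (nrow(probes) > 0L) {
    ov <- find_region_overlaps(probes, span)
    tab <- table(ov$subject)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  data.frame(gene_id = genes$gene_id, n_probes = counts,
             stringsAsFactors = FALSE)
}

#' Intersect two peak sets
#'
#' Genomic intersection (bases covered in both sets), for deriving
#' replicate-conserved peak regions before probe design.
#'
#' @param a,b Interval data.frames.
#' @return Interval data.frame of the shared regions.
#' @export
intersect_peaks <- function(a, b) {
  check_regions(a, "a"); check_regions(b, "b")
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  ga <- GenomicRanges::reduce(.gr(a))
  gb <- GenomicRanges::reduce(.gr(b))
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv; GenomeInfoDb::seqlevels(gb) <- lv
  gi <- GenomicRanges::intersect(ga, gb)
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gi)),
             start = GenomicRanges::start(gi) - 1,
             end = as.numeric(GenomicRanges::end(gi)),
             stringsAsFactors = FALSE)
}
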