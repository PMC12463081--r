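#' In-silico restriction digestion of a genome
#'
#' Cuts each chromosome immediately 5' of every occurrence of the
#' recognition site (default `GATC`, DpnII) and returns the maximal
#' fragments between cuts. Fragments tile each chromosome exactly:
#' they are sorted, non-overlapping, gap-free, and their concatenation
#' reconstructs `[0, chrom_length)`. Zero-length fragments (a site at
#' position 0) are dropped. IUPAC ambiguity codes in the sequence never
#' match the site.
#'
#' @param genome Named character vector or `DNAStringSet` of
#'   chromosome sequences (case-insensitive).
#' @param site Recognition sequence (default `"GATC"`).
#' @return Fragment data.frame with columns `fragment_id` (stable
#'   integer index, unique genome-wide, ordered by chromosome then
#'   start), `chrom`, `start`, `end`. Chromosome lengths are attached
#'   as attribute `chrom_lengths`.
#' @examples
#' digest_genome(c(chrA = "AAGATCAA")) # fragments [0,2) and [2,8)
#' @export
digest_genome <- function(genome, site = "GATC") {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome sequences must be named by chromosome")
  }
  if (!nzchar(site)) stop("recognition site must be nonempty")
  site <- toupper(site)
  pieces <- vector("list", length(genome))
  lens <- numeric(length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    seq <- toupper(genome[[i]])
    len <- nchar(seq)
    lens[i] <- len
    if (len == 0L) {
      warning("chromosome ", chrom, " is empty; no fragments produced")
      pieces[[i]] <- data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0))
      next
    }
    m <- Biostrings::matchPattern(Biostrings::DNAString(site),
                                  Biostrings::DNAString(seq), fixed = TRUE)
    cuts <- BiocGenerics::start(m) - 1L  # 0-based cut positions, 5' of site
    bounds <- sort(unique(c(0L, as.integer(cuts), as.integer(len))))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    keep <- ends > starts
    pieces[[i]] <- data.frame(chrom = chrom, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- cbind(fragment_id = seq_len(nrow(out)), out)
  attr(out, "chrom_lengths") <- setNames(lens, names(genome))
  out
}

# Fast sanity check of the tiling invariant; used by consumers that
# require a valid fragment map.
check_fragments <- function(fragments) {
  check_regions(fragments, "fragments")
  if (!"fragment_id" %in% names(fragments)) {
    stop("fragments must carry a fragment_id column")
  }
  if (anyDuplicated(fragments$fragment_id) > 0L) {
    stop("fragment_id values must be unique")
  }
  for (cr in unique(fragments$chrom)) {
    sub <- fragments[fragments$chrom == cr, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] != sub$end[-nrow(sub)])) {
      stop("fragments do not tile chromosome ", cr)
    }
  }
  invisible(fragments)
}

#' Map regions to the restriction fragments they overlap
#'
#' Returns the id of every fragment sharing at least `min_overlap`
#' bases with at least one region; this is how probe-covered (bait)
#' fragments are derived from peak calls.
#'
#' @param regions Interval data.frame (e.g. peaks).
#' @param fragments Fragment map from [digest_genome()].
#' @param min_overlap Minimum shared bases (default 1).
#' @return Sorted vector of unique `fragment_id`s.
#' @export
map_regions_to_fragments <- function(regions, fragments, min_overlap = 1L) {
  check_regions(regions, "regions")
  check_fragments(fragments)
  if (nrow(regions) == 0L) return(integer(0))
  missing_chrom <- setdiff(unique(regions$chrom), unique(fragments$chrom))
  if (length(missing_chrom) > 0L) {
    stop("region chromosome absent from fragment map: ",
         paste(missing_chrom, collapse = ", "))
  }
  ov <- find_region_overlaps(regions, fragments, min_overlap = min_overlap)
  sort(unique(fragments$fragment_id[ov$subject]))
}

# Fragment rows for a set of ids, in id order; errors on unknown ids.
fragments_by_id <- function(fragments, ids) {
  idx <- match(ids, fragments$fragment_id)
  if (any(is.na(idx))) {
    stop("unknown fragment_id: ", ids[which(is.na(idx))[1L]])
  }
  fragments[idx, , drop = FALSE]
}
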