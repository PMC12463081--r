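#' Construct a table of genomic intervals
#'
#' Intervals are plain `data.frame`s with columns `chrom`, `start`,
#' `end` and optionally `strand`, using 0-based half-open coordinates:
#' `start` is the first base of the interval and `end` is one past the
#' last. An interval must satisfy `0 <= start < end`.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (default `"."`).
#' @param ... Further columns recycled to the interval count
#'   (e.g. `name`, `score`).
#' @return A validated `data.frame` of intervals.
#' @examples
#' regions("chr1", c(0, 500), c(100, 900))
#' @export
regions <- function(chrom, start, end, strand = ".", ...) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  strand = strand,
                  stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) x[[nm]] <- extra[[nm]]
  check_regions(x)
  x
}

# Validate an interval data.frame; errors name the first offending row.
check_regions <- function(x, what = "regions") {
  if (!is.data.frame(x)) stop(what, " must be a data.frame")
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss) > 0L) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    stop(what, ": chromosome names must be nonempty")
  }
  bad <- which(is.na(x$start) | is.na(x$end) | x$start < 0 | x$start >= x$end)
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid interval at row %d (need 0 <= start < end)",
                 what, bad[1L]))
  }
  if ("strand" %in% names(x)) {
    if (any(!x$strand %in% c("+", "-", "."))) {
      stop(what, ": strand must be one of '+', '-', '.'")
    }
  }
  invisible(x)
}

# Internal: convert an interval data.frame to GRanges (1-based closed).
# Strand is always dropped; overlap queries are strand-blind.
.gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = as.integer(x$start) + 1L,
                              end = as.integer(x$end))
  )
}

#' Test whether two intervals overlap
#'
#' Half-open overlap on the same chromosome: `a` and `b` overlap iff
#' they share at least `min_overlap` bases, i.e.
#' `a$start < b$end && b$start < a$end` (for `min_overlap = 1`).
#' Symmetric and strand-blind. Vectorized over rows (pairwise).
#'
#' @param a,b Interval data.frames with the same number of rows (or one
#'   of them a single row, recycled).
#' @param min_overlap Minimum shared bases required (default 1).
#' @return Logical vector.
#' @examples
#' overlaps(regions("chr1", 0, 100), regions("chr1", 100, 200)) # FALSE
#' overlaps(regions("chr1", 0, 100), regions("chr1", 99, 200))  # TRUE
#' @export
overlaps <- function(a, b, min_overlap = 1L) {
  check_regions(a, "a"); check_regions(b, "b")
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  same <- as.character(a$chrom)[ia] == as.character(b$chrom)[ib]
  shared <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib])
  same & shared >= min_overlap
}

#' Find all overlapping pairs between two interval sets
#'
#' The workhorse overlap engine (backed by [GenomicRanges]); returns
#' every (query, subject) index pair sharing at least `min_overlap`
#' bases on the same chromosome, together with the shared width.
#'
#' @param query,subject Interval data.frames.
#' @param min_overlap Minimum shared bases (default 1).
#' @return A data.frame with columns `query`, `subject`, `overlap_bp`.
#' @export
find_region_overlaps <- function(query, subject, min_overlap = 1L) {
  check_regions(query, "query"); check_regions(subject, "subject")
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = numeric(0)))
  }
  qg <- .gr(query); sg <- .gr(subject)
  lv <- union(GenomeInfoDb::seqlevels(qg), GenomeInfoDb::seqlevels(sg))
  GenomeInfoDb::seqlevels(qg) <- lv
  GenomeInfoDb::seqlevels(sg) <- lv
  hits <- GenomicRanges::findOverlaps(qg, sg, minoverlap = min_overlap)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  data.frame(
    query = qi,
    subject = si,
    overlap_bp = pmin(query$end[qi], subject$end[si]) -
      pmax(query$start[qi], subject$start[si])
  )
}

#' Promoter windows of gene models
#'
#' The promoter is the fixed-width window immediately upstream of the
#' strand-aware gene start: `[start - width, start)` for `+` genes and
#' `[end, end + width)` for `-` genes. Windows are clipped at 0.
#'
#' @param genes Gene interval data.frame with `strand`.
#' @param width Promoter width in bp (default 1000).
#' @return Interval data.frame with a `gene_id` column when present in
#'   the input.
#' @export
promoter_regions <- function(genes, width = 1000L) {
  check_regions(genes, "genes")
  if (!"strand" %in% names(genes)) stop("genes must carry a strand column")
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$end, pmax(0, genes$start - width))
  end <- ifelse(minus, genes$end + width, genes$start)
  out <- data.frame(chrom = genes$chrom, start = start, end = end,
                    strand = genes$strand, stringsAsFactors = FALSE)
  if ("gene_id" %in% names(genes)) out$gene_id <- genes$gene_id
  # a + gene starting at 0 has an empty promoter; drop such rows
  out[out$start < out$end, , drop = FALSE]
}

# Interval midpoints (numeric, may end in .5).
region_midpoints <- function(x) (x$start + x$end) / 2
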