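# Readers and writers for the small set of plain-text formats the
# pipeline consumes: BED3/6, bedGraph, BEDPE-like loop tables, GFF3
# gene subsets, FASTA, and simple TSVs. All writers emit a leading
# comment line with the tool version; all readers tolerate comment,
# track and browser lines. Malformed lines are reported with their
# line number.

version_header <- function() sprintf("# pcgloop %s", pcgloop_version())

.skip_line <- function(lines) {
  grepl("^#", lines) | grepl("^track( |$)", lines) | grepl("^browser( |$)", lines) |
    !nzchar(trimws(lines))
}

# Split kept lines into fields, retaining original line numbers.
.read_table_lines <- function(path, what) {
  if (!file.exists(path)) stop(what, " file does not exist: ", path)
  lines <- readLines(path)
  keep <- !.skip_line(lines)
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

.field_num <- function(x, lineno, path, col) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0L) {
    stop(sprintf("%s: non-numeric %s field at line %d", path, col,
                 lineno[bad[1L]]))
  }
  v
}

#' Read a BED3/BED6 file
#'
#' Comment (`#`), `track` and `browser` lines are skipped. Lines with
#' fewer than 3 fields or with `start >= end` raise an error naming the
#' line number.
#'
#' @param path Path to a BED file.
#' @return Interval data.frame, with `name`, `score`, `strand` when the
#'   file has 6 columns.
#' @export
read_bed <- function(path) {
  tl <- .read_table_lines(path, "BED")
  nf <- lengths(tl$fields)
  if (length(nf) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  if (any(nf < 3L)) {
    stop(sprintf("%s: fewer than 3 fields at line %d", path,
                 tl$lineno[which(nf < 3L)[1L]]))
  }
  get <- function(i) vapply(tl$fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  out <- data.frame(chrom = get(1),
                    start = .field_num(get(2), tl$lineno, path, "start"),
                    end = .field_num(get(3), tl$lineno, path, "end"),
                    stringsAsFactors = FALSE)
  if (all(nf >= 6L)) {
    out$name <- get(4)
    out$score <- .field_num(get(5), tl$lineno, path, "score")
    out$strand <- ifelse(get(6) %in% c("+", "-"), get(6), ".")
  } else if (all(nf >= 4L)) {
    out$name <- get(4)
  }
  bad <- which(out$start < 0 | out$start >= out$end)
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid interval (start >= end) at line %d", path,
                 tl$lineno[bad[1L]]))
  }
  out
}

#' Write intervals as BED
#'
#' Writes BED6 when `name` is present (missing `score`/`strand` filled
#' with 0 and `.`), else BED3. A version comment line leads the file.
#'
#' @param x Interval data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  check_regions(x, "x")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(version_header(), con)
  if (nrow(x) == 0L) return(invisible(path))
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x)) {
    score <- if ("score" %in% names(x)) x$score else 0
    strand <- if ("strand" %in% names(x)) x$strand else "."
    cols <- c(cols, list(x$name, score, strand))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Four tab-separated columns: chrom, start, end, value. The track is
#' sorted on load; overlapping intervals within a chromosome are an
#' error (a coverage track must be a step function). Values must be
#' finite and nonnegative.
#'
#' @param path Path to a bedGraph file.
#' @return Data.frame `chrom`, `start`, `end`, `value`, sorted.
#' @export
read_bedgraph <- function(path) {
  tl <- .read_table_lines(path, "bedGraph")
  nf <- lengths(tl$fields)
  if (length(nf) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  }
  if (any(nf < 4L)) {
    stop(sprintf("%s: fewer than 4 fields at line %d", path,
                 tl$lineno[which(nf < 4L)[1L]]))
  }
  get <- function(i) vapply(tl$fields, `[`, "", i)
  out <- data.frame(chrom = get(1),
                    start = .field_num(get(2), tl$lineno, path, "start"),
                    end = .field_num(get(3), tl$lineno, path, "end"),
                    value = .field_num(get(4), tl$lineno, path, "value"),
                    stringsAsFactors = FALSE)
  bad <- which(out$start < 0 | out$start >= out$end)
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid interval at line %d", path, tl$lineno[bad[1L]]))
  }
  if (any(!is.finite(out$value) | out$value < 0)) {
    stop(path, ": bedGraph values must be finite and >= 0")
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  check_track(out, path)
  out
}

# Assert the non-overlap invariant of a signal track.
check_track <- function(track, what = "track") {
  for (cr in unique(track$chrom)) {
    sub <- track[track$chrom == cr, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop(what, ": overlapping intervals on chromosome ", cr)
    }
  }
  invisible(track)
}

#' @rdname read_bedgraph
#' @param x Track data.frame.
#' @export
write_bedgraph <- function(x, path) {
  check_regions(x, "x")
  if (!"value" %in% names(x)) stop("track must carry a value column")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(version_header(), con)
  if (nrow(x) > 0L) {
    writeLines(paste(x$chrom,
                     format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE),
                     format(x$value, scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read/write BEDPE-like loop tables
#'
#' Loops are pairs of anchor intervals, tab-separated with columns
#' `chromA,startA,endA,chromB,startB,endB,score`. Extra annotation
#' columns (classes, fates) survive a round trip via a commented header
#' line. Readers tolerate comment lines; the column-name line starts
#' with `#chromA`.
#'
#' @param path File path.
#' @return Data.frame of anchor pairs.
#' @export
read_loop_table <- function(path) {
  if (!file.exists(path)) stop("loop table does not exist: ", path)
  lines <- readLines(path)
  hdr <- grep("^#chromA\t", lines, value = TRUE)
  cn <- if (length(hdr) > 0L) strsplit(sub("^#", "", hdr[1L]), "\t")[[1L]] else
    c("chromA", "startA", "endA", "chromB", "startB", "endB", "score")
  keep <- which(!.skip_line(lines))
  if (length(keep) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cn)), cn))
    return(out)
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cn))) {
    stop(sprintf("%s: expected %d fields, got %d at line %d", path,
                 length(cn), nf[which(nf != length(cn))[1L]],
                 keep[which(nf != length(cn))[1L]]))
  }
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- cn
  numcols <- intersect(c("startA", "endA", "startB", "endB", "score",
                         "anchorA", "anchorB", "loop_id"), cn)
  for (col in numcols) out[[col]] <- as.numeric(out[[col]])
  lgl <- intersect(c("hub_member", "nonbait_k27", "trans"), cn)
  for (col in lgl) out[[col]] <- as.logical(out[[col]])
  bad <- which(out$startA < 0 | out$startA >= out$endA |
                 out$startB < 0 | out$startB >= out$endB)
  if (length(bad) > 0L) {
    stop(sprintf("%s: invalid anchor interval at line %d", path, keep[bad[1L]]))
  }
  out
}

#' @rdname read_loop_table
#' @param x Loop table.
#' @export
write_loop_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(version_header(), con)
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  if (nrow(x) > 0L) {
    mat <- vapply(x, function(col) {
      if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE)
      else as.character(col)
    }, FUN.VALUE = character(nrow(x)))
    if (nrow(x) == 1L) mat <- matrix(mat, nrow = 1L)
    writeLines(apply(mat, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features (exons may point at a gene
#' directly or through an intermediate mRNA `Parent`). GFF3 1-based
#' closed coordinates are converted to the package's 0-based half-open
#' convention on read.
#'
#' @param path Path to a GFF3 file.
#' @return A list with data.frames `genes` (`gene_id`, interval,
#'   strand) and `exons` (`gene_id`, interval).
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file does not exist: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  gidx <- which(type == "gene")
  genes <- data.frame(
    gene_id = ids[gidx],
    chrom = as.character(GenomeInfoDb::seqnames(gr))[gidx],
    start = GenomicRanges::start(gr)[gidx] - 1,
    end = as.numeric(GenomicRanges::end(gr))[gidx],
    strand = as.character(GenomicRanges::strand(gr))[gidx],
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "."
  # resolve exon Parent -> gene, possibly via mRNA
  parent_of <- function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }
  mrna <- which(type == "mRNA")
  mrna_gene <- setNames(vapply(mrna, parent_of, ""), ids[mrna])
  eidx <- which(type == "exon")
  egene <- vapply(eidx, parent_of, "")
  via <- egene %in% names(mrna_gene)
  egene[via] <- mrna_gene[egene[via]]
  exons <- data.frame(
    gene_id = egene,
    chrom = as.character(GenomeInfoDb::seqnames(gr))[eidx],
    start = GenomicRanges::start(gr)[eidx] - 1,
    end = as.numeric(GenomicRanges::end(gr))[eidx],
    stringsAsFactors = FALSE
  )
  list(genes = genes, exons = exons)
}

#' Write gene models as GFF3
#'
#' @param genes Gene interval data.frame with `gene_id` and `strand`.
#' @param exons Exon interval data.frame with `gene_id`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, exons, path) {
  check_regions(genes, "genes"); check_regions(exons, "exons")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(version_header(), con)
  for (i in seq_len(nrow(genes))) {
    writeLines(paste(genes$chrom[i], "pcgloop", "gene",
                     format(genes$start[i] + 1, scientific = FALSE),
                     format(genes$end[i], scientific = FALSE),
                     ".", genes$strand[i], ".",
                     sprintf("ID=%s", genes$gene_id[i]), sep = "\t"), con)
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(paste(ex$chrom[j], "pcgloop", "exon",
                       format(ex$start[j] + 1, scientific = FALSE),
                       format(ex$end[j], scientific = FALSE),
                       ".", genes$strand[i], ".",
                       sprintf("ID=%s.exon%d;Parent=%s", genes$gene_id[i], j,
                               genes$gene_id[i]), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read/write genome FASTA
#'
#' Thin wrappers over Biostrings keeping sequences as a named
#' uppercase character vector (one element per chromosome).
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), names(ss))
}

#' @rdname read_fasta
#' @param genome Named character vector of sequences.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a gene expression table
#'
#' Tab-separated with a header line: `gene_id`, `expression` (plus any
#' further columns, which are kept).
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_expression <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "expression") %in% names(x))) {
    stop(path, ": expected columns gene_id and expression")
  }
  if (any(!is.finite(x$expression) | x$expression < 0)) {
    stop(path, ": expression values must be finite and >= 0")
  }
  x
}

#' Read differential-expression labels
#'
#' Tab-separated with a header: `gene_id`, `de_label` in
#' `up`/`down`/`ns`. Labels are supplied (e.g. from a DESeq2 run), never
#' computed by this package.
#'
#' @param path TSV path.
#' @return Data.frame with `gene_id`, `de_label`.
#' @export
read_de_labels <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!all(c("gene_id", "de_label") %in% names(x))) {
    stop(path, ": expected columns gene_id and de_label")
  }
  if (any(!x$de_label %in% c("up", "down", "ns"))) {
    stop(path, ": de_label must be one of up/down/ns")
  }
  x
}

# Generic TSV with version comment; round-trips via read.table.
write_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(version_header(), con)
  suppressWarnings(utils::write.table(x, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
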