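# Interval model, digestion, overlap engine and format round-trips.

test_that("digestion cuts 5' of each site and tiles the chromosome", {
  f <- digest_genome(c(chrA = "AAGATCAA"))
  expect_equal(f$start, c(0, 2))
  expect_equal(f$end, c(2, 8))

  # site at position 0: the empty leading fragment is dropped
  f <- digest_genome(c(chrA = "GATCGATC"))
  expect_equal(f$start, c(0, 4))
  expect_equal(f$end, c(4, 8))

  # no site: one fragment spanning the chromosome
  f <- digest_genome(c(chrA = strrep("AC", 50)))
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$start, f$end), c(0, 100))

  # lowercase input, and N never matches the site
  f <- digest_genome(c(chrA = "aagatcaa", chrB = "AANATCAA"))
  expect_equal(f$start[f$chrom == "chrA"], c(0, 2))
  expect_equal(nrow(f[f$chrom == "chrB", ]), 1L)

  expect_warning(digest_genome(c(chrA = "AAGATCAA", empty = "")),
                 "empty")
})

test_that("digestion matches the naive-scan oracle on random genomes", {
  set.seed(101)
  for (rep in 1:10) {
    genome <- random_toy_genome()
    frags <- digest_genome(genome)
    expect_true(all(diff(frags$fragment_id) == 1L))
    for (cr in names(genome)) {
      sub <- frags[frags$chrom == cr, ]
      ora <- oracle_digest(genome[[cr]])
      expect_equal(sub$start, ora$start)
      expect_equal(sub$end, ora$end)
      # tiling: gap-free, sorted, sums to chromosome length
      expect_equal(sum(sub$end - sub$start), nchar(genome[[cr]]))
      expect_true(all(sub$start[-1L] == sub$end[-nrow(sub)]))
    }
  }
})

test_that("pairwise overlap follows the half-open convention", {
  a <- regions("chr1", 0, 100)
  expect_false(overlaps(a, regions("chr1", 100, 200)))  # touching
  expect_true(overlaps(a, regions("chr1", 99, 200)))    # 1 bp shared
  expect_false(overlaps(a, regions("chr2", 0, 100)))    # other chrom
  expect_equal(overlaps(a, regions("chr1", 99, 200)),
               overlaps(regions("chr1", 99, 200), a))   # symmetric
  # configurable minimum overlap
  expect_false(overlaps(a, regions("chr1", 99, 200), min_overlap = 2))
})

test_that("overlap engine equals the all-pairs oracle on random sets", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(1:200, 1L); m <- sample(1:200, 1L)
    mk <- function(k) {
      s <- sample(0:5000, k, replace = TRUE)
      data.frame(chrom = sample(c("c1", "c2", "c3"), k, replace = TRUE),
                 start = s, end = s + sample(1:400, k, replace = TRUE))
    }
    a <- mk(n); b <- mk(m)
    got <- find_region_overlaps(a, b)
    got <- got[order(got$query, got$subject), ]
    ora <- oracle_overlap_pairs(a, b)
    expect_equal(got$query, ora$query)
    expect_equal(got$subject, ora$subject)
    expect_equal(got$overlap_bp, ora$overlap_bp)
  }
})

test_that("regions map to every overlapping fragment", {
  frags <- data.frame(fragment_id = 1:2, chrom = "chr1",
                      start = c(0, 50), end = c(50, 100))
  expect_equal(map_regions_to_fragments(regions("chr1", 10, 20), frags), 1L)
  expect_equal(map_regions_to_fragments(regions("chr1", 40, 60), frags),
               c(1L, 2L))
  expect_equal(map_regions_to_fragments(regions("chr1", 0, 1)[0, ], frags),
               integer(0))
  expect_error(map_regions_to_fragments(regions("chrX", 0, 10), frags),
               "chrX")
})

test_that("BED round-trips losslessly and rejects malformed lines", {
  x <- regions(c("chr1", "chr1", "chr2"), c(0, 500, 20), c(100, 900, 80),
               strand = c("+", "-", "."), name = c("a", "b", "c"),
               score = c(1, 2.5, 0))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y[c("chrom", "start", "end", "name", "score", "strand")],
               x[c("chrom", "start", "end", "name", "score", "strand")])

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment", "chr1\t100\t50"), bad)
  expect_error(read_bed(bad), "line 2")
})

test_that("bedGraph is sorted on load and overlapping intervals error", {
  path <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("track type=bedGraph", "chr1\t50\t100\t2.5",
               "chr1\t0\t50\t1"), path)
  tr <- read_bedgraph(path)
  expect_equal(tr$start, c(0, 50))
  expect_equal(tr$value, c(1, 2.5))

  writeLines(c("chr1\t0\t60\t1", "chr1\t50\t100\t2"), path)
  expect_error(read_bedgraph(path), "overlapping")
})

test_that("loop tables round-trip including annotation columns", {
  x <- data.frame(chromA = "chr1", startA = c(0, 200), endA = c(100, 300),
                  chromB = "chr1", startB = c(5000, 9000),
                  endB = c(5100, 9100), score = c(11.5, 3),
                  final_class = c("PCGHUB_BOTH", "PURE_ONLY_H2AUB"),
                  stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_loop_table(x, path)
  y <- read_loop_table(path)
  expect_equal(y, x)
})

test_that("GFF3 gene models round-trip and promoters are strand-aware", {
  genes <- regions("chr1", c(1000, 5000), c(3000, 6000),
                   strand = c("+", "-"), gene_id = c("g1", "g2"))
  exons <- regions("chr1", c(1000, 2500, 5000), c(1600, 3000, 6000),
                   gene_id = c("g1", "g1", "g2"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, exons, path)
  gm <- read_gff_genes(path)
  expect_equal(gm$genes$gene_id, genes$gene_id)
  expect_equal(gm$genes$start, genes$start)
  expect_equal(gm$genes$end, genes$end)
  expect_equal(gm$genes$strand, genes$strand)
  expect_equal(gm$exons$start[gm$exons$gene_id == "g1"], c(1000, 2500))

  # minus-strand gene at [5000,6000): promoter is [6000,7000)
  prom <- promoter_regions(gm$genes, 1000)
  p2 <- prom[prom$gene_id == "g2", ]
  expect_equal(c(p2$start, p2$end), c(6000, 7000))
  p1 <- prom[prom$gene_id == "g1", ]
  expect_equal(c(p1$start, p1$end), c(0, 1000))
})

test_that("FASTA round-trips sequences by chromosome", {
  genome <- c(chr1 = "ACGTGATCAAAT", chr2 = "TTTT")
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(genome, path)
  expect_equal(read_fasta(path), genome)
})
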