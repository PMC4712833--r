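test_that("read_bed parses the three dialects and validates coordinates", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "chr1\t50\t150", "chr1\t0\t100",
               "chr2\t10\t20"), p)
  x <- read_bed(p)
  expect_equal(nrow(x), 3)
  expect_equal(x$start, c(0L, 50L, 10L))          # sorted by chrom, start
  expect_equal(x$chrom, c("chr1", "chr1", "chr2"))

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t300\tpk\t500\t.\t8.2\t-1\t-1\t25", np)
  y <- read_bed(np, dialect = "narrowPeak")
  expect_equal(y$summit_offset, 25L)
  expect_equal(interval_anchor(y), 125L)          # absolute summit position

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\t100"), bad)
  expect_error(read_bed(bad), "line 2")
  writeLines("chr1\tx\t100", bad)
  expect_error(read_bed(bad), "malformed")
})

test_that("BED round-trip through write_bed preserves the collection", {
  withr::local_seed(11)
  x <- random_intervals(40)
  x$score <- round(runif(40), 3)
  x$strand <- sample(c("+", "-", "."), 40, replace = TRUE)
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, p)
  y <- read_bed(p, dialect = "bed6")
  expect_equal(y$chrom, x$chrom)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$name, x$name)
  expect_equal(y$score, x$score)
  expect_equal(y$strand, x$strand)
})

test_that("read_tss handles both formats, strand conventions and duplicates", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneA\tchr1\t1000\t+", "geneA\tchr1\t1000\t+",
               "geneB\tchr1\t2000\t-"), p)
  x <- read_tss(p)
  expect_equal(nrow(x), 2)                        # duplicate collapsed
  expect_equal(x$tss[x$gene_id == "geneA"], 1000L)

  g <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "transcript", "2001", "3000", ".", "-", ".",
          'gene_id "gX";', sep = "\t"),
    paste("chr1", "src", "exon", "2001", "2100", ".", "-", ".",
          'gene_id "gX";', sep = "\t")), g)
  y <- read_tss(g, format = "gtf_lite")
  expect_equal(nrow(y), 1)                        # exon row ignored
  expect_equal(y$tss, 2999L)                      # minus strand: end - 1

  writeLines("geneA\tchr1\t1000\t.", p)
  expect_error(read_tss(p), "strand")
  writeLines(character(), p)
  expect_warning(z <- read_tss(p), "no TSS")
  expect_equal(nrow(z), 0)
})

test_that("query_overlaps obeys half-open arithmetic and min_overlap", {
  coll <- itbl("chr1", c(0, 140, 200), c(100, 160, 300))
  probe <- itbl("chr1", 50, 150)
  hit <- query_overlaps(coll, probe)
  expect_equal(hit$start, c(0L, 140L))            # overlaps of 50 and 10 bp
  expect_equal(nrow(query_overlaps(coll, probe, min_overlap = 60)), 0)
  expect_equal(nrow(query_overlaps(coll, itbl("chrX", 50, 150))), 0)
  expect_error(query_overlaps(coll, probe, min_overlap = 0), "min_overlap")
})

test_that("query_overlaps matches a quadratic brute-force scan", {
  withr::local_seed(42)
  for (rep in 1:200) {
    coll <- random_intervals(sample(1:30, 1))
    probe <- random_intervals(1)
    mo <- sample(c(1, 5, 50, 200), 1)
    got <- query_overlaps(coll, probe, min_overlap = mo)
    want <- brute_overlaps(coll, probe, min_overlap = mo)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("nearest-TSS distances are signed, strand-oriented and tie-broken", {
  tss <- tibble::tibble(gene_id = c("geneA", "geneB"), chrom = "chr1",
                        tss = c(1000L, 2000L), strand = c("+", "-"))
  pk <- itbl("chr1", 1400, 1600)                  # midpoint 1500
  near_a <- distance_to_nearest_tss(pk, tss[1, ])
  expect_equal(near_a$nearest_gene, "geneA")
  expect_equal(near_a$tss_distance, 500L)         # downstream of + gene
  near_b <- distance_to_nearest_tss(pk, tss[2, ])
  expect_equal(near_b$tss_distance, 500L)         # upstream in genome = downstream of - gene
  both <- distance_to_nearest_tss(pk, tss)
  expect_equal(both$nearest_gene, "geneA")        # equidistant: lexicographic

  expect_error(distance_to_nearest_tss(pk, tss[0, ]), "empty")
  off <- distance_to_nearest_tss(itbl("chrZ", 0, 10), tss)
  expect_true(is.na(off$nearest_gene))            # unassigned sentinel
})

test_that("nearest-TSS assignment matches the exhaustive scan", {
  withr::local_seed(7)
  for (rep in 1:30) {
    tss <- random_tss(sample(2:100, 1))
    peaks <- random_intervals(20)
    got <- distance_to_nearest_tss(peaks, tss, anchor = "midpoint")
    for (i in seq_len(nrow(peaks))) {
      mid <- peaks$start[i] + (peaks$end[i] - peaks$start[i]) %/% 2
      want <- brute_nearest_tss(tss, peaks$chrom[i], mid)
      expect_identical(got$nearest_gene[i], want$gene)
      expect_identical(got$tss_distance[i], want$dist)
    }
  }
})

test_that("nearest-TSS distances are invariant under coordinate translation", {
  withr::local_seed(3)
  tss <- random_tss(30, chroms = "chr1")
  peaks <- random_intervals(20, chroms = "chr1")
  base <- distance_to_nearest_tss(peaks, tss)
  shift <- 5000L
  tss2 <- dplyr::mutate(tss, tss = tss + shift)
  peaks2 <- dplyr::mutate(peaks, start = start + shift, end = end + shift)
  moved <- distance_to_nearest_tss(peaks2, tss2)
  expect_equal(moved$nearest_gene, base$nearest_gene)
  expect_equal(moved$tss_distance, base$tss_distance)
})

test_that("interval_tbl enforces its invariants", {
  expect_error(itbl("chr1", 100, 100), "start < end")
  expect_error(itbl("chr1", 10, 20, summit_offset = 10), "summit_offset")
  expect_error(itbl("chr1", 10, 2000, genome = c(chr1 = 1000)),
               "past chromosome length")
})
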