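test_that("bedGraph rasterization is a length-weighted mean with zero gaps", {
  p <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines("chr1\t0\t100\t5.0", p)
  tr <- read_bedgraph(p, bin_width = 10)
  expect_equal(tr$signal$chr1, rep(5, 10))

  writeLines("chr1\t5\t15\t10", p)
  tr2 <- read_bedgraph(p, bin_width = 10)
  expect_equal(tr2$signal$chr1, c(5, 5))           # half of each bin covered

  # record order does not matter
  writeLines(c("chr1\t50\t60\t2", "chr1\t0\t10\t4"), p)
  fwd <- read_bedgraph(p, bin_width = 10)
  writeLines(c("chr1\t0\t10\t4", "chr1\t50\t60\t2"), p)
  expect_equal(read_bedgraph(p, bin_width = 10)$signal, fwd$signal)

  writeLines("chr1\t0\t10\t-3", p)
  expect_error(read_bedgraph(p), "negative")
  writeLines(c("chr1\t0\t20\t1", "chr1\t10\t30\t1"), p)
  expect_error(read_bedgraph(p), "overlapping")
})

test_that("bedGraph round-trip preserves the binned track", {
  withr::local_seed(61)
  sig <- list(chr1 = rpois(200, 2), chr2 = rpois(80, 5))
  tr <- coverage_track(lapply(sig, as.numeric), bin_width = 10)
  p <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, p)
  back <- read_bedgraph(p, bin_width = 10,
                        genome = c(chr1 = 2000, chr2 = 800))
  expect_equal(back$signal$chr1, tr$signal$chr1)
  expect_equal(back$signal$chr2, tr$signal$chr2)
})

one_gene_tss <- function(pos, strand = "+", gene = "g1") {
  tibble::tibble(gene_id = gene, chrom = "chr1", tss = as.integer(pos),
                 strand = strand)
}

test_that("caller recovers planted flanking bumps within the bin tolerance", {
  tss_pos <- 5000
  tr <- bump_track(10000, c(tss_pos - 300, tss_pos + 289))
  call <- call_flanking_nucleosomes(tr, one_gene_tss(tss_pos))
  expect_equal(call$status, "ok")
  expect_equal(call$distance, 589, tolerance = 20 / 589)  # within 2 bins
  expect_lt(abs(call$minus1 - (tss_pos - 300)), 20)
  expect_lt(abs(call$plus1 - (tss_pos + 289)), 20)
})

test_that("flat coverage and out-of-range windows give no-calls", {
  flat <- coverage_track(list(chr1 = rep(0, 500)), bin_width = 10)
  expect_equal(call_flanking_nucleosomes(flat, one_gene_tss(2500))$status,
               "no_call")
  tr <- bump_track(10000, c(4700, 5300))
  edge <- call_flanking_nucleosomes(tr, one_gene_tss(500))
  expect_equal(edge$status, "no_call")
  expect_match(edge$reason, "outside")
  # a single bump on one side only is not a flanking pair
  one_side <- bump_track(10000, 5300)
  expect_equal(call_flanking_nucleosomes(one_side,
                                         one_gene_tss(5000))$status,
               "no_call")
})

test_that("minus-strand genes flip the +1/-1 axis in genome coordinates", {
  tss_pos <- 5000
  tr <- bump_track(10000, c(tss_pos - 250, tss_pos + 350))
  plus <- call_flanking_nucleosomes(tr, one_gene_tss(tss_pos, "+"))
  minus <- call_flanking_nucleosomes(tr, one_gene_tss(tss_pos, "-"))
  expect_gt(plus$plus1, plus$minus1)               # +1 right of TSS
  expect_lt(minus$plus1, minus$minus1)             # +1 left of TSS
  expect_equal(plus$distance, minus$distance)      # spacing is strandless
})

test_that("calls are equivariant under translation and locus mirroring", {
  tss_pos <- 3000
  tr <- bump_track(20000, c(tss_pos - 280, tss_pos + 310))
  base <- call_flanking_nucleosomes(tr, one_gene_tss(tss_pos))
  shift <- 7000
  tr_shift <- bump_track(20000, c(tss_pos + shift - 280,
                                  tss_pos + shift + 310))
  moved <- call_flanking_nucleosomes(tr_shift, one_gene_tss(tss_pos + shift))
  expect_equal(moved$distance, base$distance)
  expect_equal(moved$plus1 - shift, base$plus1)
  # mirror the whole locus around the TSS and flip the strand
  tr_mirror <- bump_track(20000, c(tss_pos - 310, tss_pos + 280))
  mirrored <- call_flanking_nucleosomes(tr_mirror,
                                        one_gene_tss(tss_pos, "-"))
  expect_equal(mirrored$distance, base$distance, tolerance = 10 / 590)
})

test_that("spacing comparison: identical calls give p = 1, shifts are exact", {
  withr::local_seed(67)
  calls <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10), strand = "+",
    minus1 = 1000, plus1 = 1000 + round(rnorm(10, 589, 60)),
    distance = plus1 - minus1, prom_minus = 1, prom_plus = 1,
    status = "ok", reason = NA_character_)
  expect_warning(same <- compare_spacing(calls, calls), "degenerate")
  expect_equal(same$test$p_value, 1)
  expect_equal(same$median_a, same$median_b)

  shifted <- dplyr::mutate(calls, distance = distance - 100)
  comp <- compare_spacing(calls, shifted)
  expect_equal(comp$test$p_value, 2 / 1024)        # all-positive, n = 10
  expect_equal(comp$median_a - comp$median_b, 100)
  expect_error(compare_spacing(calls[1:4, ], calls), "need >= 6")
})

test_that("planted spacing medians are recovered on synthetic tracks", {
  for (m in c(400, 589, 800)) {
    cfg <- synthetic_config(seed = 70 + m, n_chrom = 1, n_genes = 300,
                            n_peaks = 10,
                            spacing = list(a = list(median = m, sd = 60)))
    gt <- generate_genome(cfg)
    cv <- generate_coverage(cfg, gt)
    calls <- call_flanking_nucleosomes(cv$tracks$a, gt$tss)
    ok <- calls$status == "ok"
    expect_gt(mean(ok), 0.95)
    recovered <- median(calls$distance[ok])
    planted <- median(cv$truth$spacing[match(calls$gene_id[ok],
                                             cv$truth$gene_id)])
    expect_lt(abs(recovered - planted), 20)        # two bin widths
  }
})
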