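# TSS fixture: two genes far enough apart that proximity is unambiguous.
fixture_tss <- tibble::tibble(
  gene_id = c("gA", "gB"), chrom = "chr1", tss = c(5000L, 50000L),
  strand = c("+", "-"))

test_that("proximal/distal split uses |anchor - TSS| <= threshold", {
  pk <- itbl("chr1", c(5200, 5901, 5902), c(5400, 6101, 6102))
  # midpoints 5300 (d=300), 6001 (d=1001), 6002 (d=1002)
  out <- split_proximal_distal(pk, fixture_tss)
  expect_equal(out$locality, c("proximal", "distal", "distal"))
  # exactly at the boundary: 1000 is proximal
  pk2 <- itbl("chr1", 5900, 6100)                 # midpoint 6000
  expect_equal(split_proximal_distal(pk2, fixture_tss)$locality, "proximal")
  expect_warning(empty <- split_proximal_distal(pk[0, ], fixture_tss),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("proximal categories follow the mark co-occurrence rules", {
  pk <- itbl("chr1", c(1000, 2000, 3000, 4000), c(1300, 2300, 3300, 4300))
  on_peak <- function(i) itbl("chr1", pk$start[i] + 10, pk$end[i] - 10)
  k4me3 <- dplyr::bind_rows(on_peak(1), on_peak(2), on_peak(3))
  k27ac <- dplyr::bind_rows(on_peak(1), on_peak(3))
  k27me3 <- dplyr::bind_rows(on_peak(2), on_peak(3))
  got <- classify_proximal(pk, k4me3, k27ac, k27me3)
  expect_equal(got$category, c("active", "bivalent", "bivalent", "other"))
  # peak 3 satisfies both rules: label bivalent, both tallies flagged
  expect_true(got$rule_active[3] && got$rule_bivalent[3])
  # empty mark sets are allowed
  none <- classify_proximal(pk, k4me3[0, ], k27ac[0, ], k27me3[0, ])
  expect_true(all(none$category == "other"))
})

test_that("distal cascade: bivalent > active > repressed > latent > isolated", {
  pk <- itbl("chr1", seq(1000, 7000, by = 1000), seq(1300, 7300, by = 1000))
  on_peak <- function(i) itbl("chr1", pk$start[i] + 10, pk$end[i] - 10)
  k4me1 <- dplyr::bind_rows(on_peak(1), on_peak(2), on_peak(4), on_peak(5))
  k27ac <- dplyr::bind_rows(on_peak(1), on_peak(2), on_peak(6))
  k27me3 <- dplyr::bind_rows(on_peak(1), on_peak(3), on_peak(4))
  got <- classify_distal(pk, k4me1, k27ac, k27me3)
  expect_equal(got$category,
               c("bivalent",   # all three marks
                 "active",     # K27Ac + K4me1, no K27me3
                 "repressed",  # K27me3 only
                 "repressed",  # K27me3 + K4me1 falls to repressed
                 "latent",     # K4me1 only
                 "other",      # K27Ac only: outside the five named classes
                 "isolated"))  # no mark at all
  strict <- classify_distal(pk, k4me1, k27ac, k27me3, strict_five = TRUE)
  expect_equal(strict$category[6], "latent")
  expect_equal(strict$category[-6], got$category[-6])
})

planted_fixture <- function(seed = 1) {
  cfg <- tiny_config(seed)
  gt <- generate_genome(cfg)
  pk <- generate_peaks(cfg, gt)
  cls <- classify_peaks(pk$peaks, gt$tss, pk$marks$k4me3, pk$marks$k4me1,
                        pk$marks$k27ac, pk$marks$k27me3)
  list(cls = cls, truth = pk$truth, tss = gt$tss)
}

test_that("every peak gets exactly one label and the split is a partition", {
  fx <- planted_fixture(4)
  expect_false(any(is.na(fx$cls$category)))
  expect_setequal(fx$cls$locality, c("proximal", "distal"))
  expect_equal(sum(fx$cls$locality == "proximal") +
                 sum(fx$cls$locality == "distal"), nrow(fx$cls))
  comp <- class_composition(fx$cls)
  expect_equal(sum(comp$n), nrow(fx$cls))
  expect_equal(sum(comp$frac_total), 1, tolerance = 1e-12)
})

test_that("classifier recovers every planted label", {
  fx <- planted_fixture(2)
  joined <- dplyr::inner_join(fx$cls[, c("name", "category")], fx$truth,
                              by = "name")
  expect_equal(joined$category.x, joined$category.y)
})

test_that("composition is invariant under peak-order shuffling", {
  fx <- planted_fixture(3)
  comp1 <- class_composition(fx$cls)
  shuffled <- fx$cls[sample(nrow(fx$cls)), ]
  comp2 <- class_composition(shuffled)
  expect_equal(comp1, comp2)
})

test_that("single-peak composition has fraction 1 and empty input is empty", {
  fx <- planted_fixture(5)
  one <- fx$cls[1, ]
  comp <- class_composition(one)
  expect_equal(comp$frac_total[comp$category == one$category], 1)
  expect_equal(nrow(class_composition(fx$cls[0, ])), 0)
})

test_that("rule-mode composition can exceed the exclusive proximal tallies", {
  # a peak overlapping K4me3 + K27Ac + K27me3 counts as active AND bivalent
  tss <- tibble::tibble(gene_id = "g", chrom = "chr1", tss = 5000L,
                        strand = "+")
  pk <- itbl("chr1", 4900, 5200)
  mk <- itbl("chr1", 4950, 5150)
  cls <- classify_peaks(pk, tss, k4me3 = mk, k4me1 = mk[0, ], k27ac = mk,
                        k27me3 = mk)
  lab <- class_composition(cls)
  rule <- class_composition(cls, mode = "rule")
  expect_equal(lab$n[lab$category == "proximal_bivalent"], 1L)
  expect_equal(lab$n[lab$category == "proximal_active"], 0L)
  expect_equal(rule$n[rule$category == "proximal_active"], 1L)
  expect_equal(rule$n[rule$category == "proximal_bivalent"], 1L)
})

test_that("peak-centered signal matrix averages the track per bin", {
  flat <- coverage_track(list(chr1 = rep(2, 1000)), bin_width = 10)
  pk <- itbl("chr1", 4000, 4300)
  m <- peak_signal_matrix(pk, flat, flank = 1000, bins = 20)
  expect_true(all(m == 2))

  # single hot track bin at the peak center: cell = area / (2 * flank)
  sig <- rep(0, 1000); sig[415] <- 7               # covers [4140, 4150)
  delta <- coverage_track(list(chr1 = sig), bin_width = 10)
  pk2 <- itbl("chr1", 4000, 4290)                  # midpoint 4145
  m2 <- peak_signal_matrix(pk2, delta, flank = 100, bins = 1)
  expect_equal(as.numeric(m2), 7 * 10 / 200)

  # window truncated by the chromosome edge: sentinel NA bins
  edge <- peak_signal_matrix(itbl("chr1", 0, 300), flat, flank = 1000,
                             bins = 4)
  expect_true(anyNA(edge))
  expect_warning(absent <- peak_signal_matrix(itbl("chrZ", 0, 300), flat,
                                              flank = 100, bins = 2),
                 "absent")
  expect_true(all(is.na(absent)))
})

test_that("signal matrix equals a naive per-base oracle", {
  withr::local_seed(21)
  for (rep in 1:15) {
    nb <- 400
    bw <- 10
    sig <- rpois(nb, 3)
    track <- coverage_track(list(chr1 = sig), bin_width = bw)
    center <- sample(1000:3000, 1)
    pk <- itbl("chr1", center - 50, center + 50)
    flank <- 200; bins <- sample(c(4, 8, 16), 1)
    m <- peak_signal_matrix(pk, track, flank = flank, bins = bins)
    per_base <- rep(sig, each = bw)                # value at every base
    edges <- (center - flank) + round(seq(0, 2 * flank,
                                          length.out = bins + 1))
    want <- vapply(seq_len(bins), function(j) {
      mean(per_base[(edges[j] + 1):edges[j + 1]])
    }, numeric(1))
    expect_equal(as.numeric(m), want)
  }
})
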