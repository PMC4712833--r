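link_fixture <- function() {
  tss <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    tss = c(10000L, 200000L, 320000L), strand = c("+", "+", "-"))
  # three proximal peaks at gA, one distal peak between gB and gC
  peaks <- itbl("chr1", c(9800, 9900, 10050, 250000),
                c(10100, 10200, 10350, 250300),
                name = paste0("p", 1:4))
  cls <- classify_peaks(peaks, tss, k4me3 = peaks[0, ], k4me1 = peaks[0, ],
                        k27ac = peaks[0, ], k27me3 = peaks[0, ])
  list(tss = tss, cls = cls)
}

test_that("proximal links deduplicate to unique genes", {
  fx <- link_fixture()
  links <- link_proximal(fx$cls)
  expect_equal(nrow(links), 3)                     # three peaks at gA
  expect_equal(unique(links$gene_id), "gA")
  expect_true(all(links$link_type == "proximal_tss"))
})

test_that("equidistant peaks break ties lexicographically", {
  tss <- tibble::tibble(gene_id = c("gB", "gA"), chrom = "chr1",
                        tss = c(1000L, 3000L), strand = "+")
  pk <- itbl("chr1", 1900, 2100)                   # midpoint 2000, both 1000 away
  cls <- classify_peaks(pk, tss, pk[0, ], pk[0, ], pk[0, ], pk[0, ])
  expect_equal(link_proximal(cls)$gene_id, "gA")
})

test_that("distal links include every TSS within the window, inclusive", {
  fx <- link_fixture()
  # distal peak anchor at 250150: gB at 50150, gC at 69850 -> both linked
  links <- link_distal(fx$cls, fx$tss, window = 100000)
  expect_setequal(links$gene_id, c("gB", "gC"))
  expect_equal(sort(links$distance), c(50150L, 69850L))
  # exact boundary: a TSS exactly `window` away is linked
  tss_b <- tibble::tibble(gene_id = "gX", chrom = "chr1", tss = 150150L,
                          strand = "+")
  exact <- link_distal(fx$cls, tss_b, window = 100000)
  expect_equal(exact$gene_id, "gX")
  just_out <- link_distal(fx$cls, dplyr::mutate(tss_b, tss = 150149L),
                          window = 100000)
  expect_equal(nrow(just_out), 0)
})

test_that("distal linkage equals the brute-force all-pairs filter", {
  withr::local_seed(47)
  for (rep in 1:10) {
    tss <- random_tss(30, max_pos = 500000)
    peaks <- random_intervals(25, max_pos = 500000)
    cls <- classify_peaks(peaks, tss, peaks[0, ], peaks[0, ], peaks[0, ],
                          peaks[0, ])
    win <- sample(c(20000, 100000), 1)
    got <- link_distal(cls, tss, window = win)
    dist_pk <- cls[cls$locality == "distal", ]
    want <- 0L
    for (i in seq_len(nrow(dist_pk))) {
      for (j in seq_len(nrow(tss))) {
        if (dist_pk$chrom[i] == tss$chrom[j] &&
            abs(dist_pk$anchor_pos[i] - tss$tss[j]) <= win) want <- want + 1L
      }
    }
    expect_equal(nrow(got), want)
  }
})

test_that("widening the distal window only adds links", {
  withr::local_seed(53)
  tss <- random_tss(40, max_pos = 400000)
  peaks <- random_intervals(30, max_pos = 400000)
  cls <- classify_peaks(peaks, tss, peaks[0, ], peaks[0, ], peaks[0, ],
                        peaks[0, ])
  small <- link_distal(cls, tss, window = 30000)
  big <- link_distal(cls, tss, window = 90000)
  key <- function(x) paste(x$peak_name, x$gene_id)
  expect_true(all(key(small) %in% key(big)))
})

test_that("proximal and distal link sets are disjoint at the peak level", {
  fx <- link_fixture()
  prox <- link_proximal(fx$cls)
  dist <- link_distal(fx$cls, fx$tss)
  expect_length(intersect(prox$peak_name, dist$peak_name), 0)
})

test_that("link/DE intersection counts unique genes by direction", {
  links <- tibble::tibble(peak_name = c("p1", "p2", "p3", "p4"),
                          gene_id = c("A", "B", "C", "B"),
                          link_type = "proximal_tss", distance = 0L,
                          category = "proximal_active")
  de <- tibble::tibble(gene_id = c("B", "C", "D"),
                       log2_fc = c(2, 1.5, 3), p_value = 0.01, fdr = 0.02,
                       direction = c("up", "up", "up"))
  got <- intersect_links_with_de(links, de)
  expect_setequal(got$up, c("B", "C"))
  expect_equal(unname(got$counts["n_up"]), 2L)
  expect_equal(unname(got$counts["n_down"]), 0L)
  expect_equal(unname(got$counts["n_linked_genes"]), 3L)

  empty_de <- de[0, ]
  none <- intersect_links_with_de(links, empty_de)
  expect_equal(unname(none$counts[c("n_up", "n_down")]), c(0L, 0L))

  bad_de <- dplyr::mutate(de, gene_id = paste0("ENS", gene_id))
  expect_error(intersect_links_with_de(links, bad_de), "mismatch")
})

test_that("planted up-linked genes are recovered through the full chain", {
  cfg <- tiny_config(6, n_genes = 150,
                     de = list(frac_up = 0.3, frac_down = 0.3,
                                  effect = 1.5, noise_sd = 0.1,
                                  n_per_group = 4L, baseline_mean = 7,
                                  baseline_sd = 1.2))
  gt <- generate_genome(cfg)
  pk <- generate_peaks(cfg, gt)
  ex <- generate_expression(cfg, gt, pk$truth)
  cls <- classify_peaks(pk$peaks, gt$tss, pk$marks$k4me3, pk$marks$k4me1,
                        pk$marks$k27ac, pk$marks$k27me3)
  de <- differential_expression(ex$expr, ex$groups, "WT", "MUT",
                                sig_mode = "p")
  got <- intersect_links_with_de(link_proximal(cls), de)
  expect_setequal(got$up, ex$truth$gene_id[ex$truth$direction == "up"])
  expect_setequal(got$down, ex$truth$gene_id[ex$truth$direction == "down"])
})
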