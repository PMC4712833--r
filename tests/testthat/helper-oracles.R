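# Independent brute-force oracles and small fixture builders. These must not
# share code with the package internals they check: overlaps and distances
# are recomputed by quadratic scans in plain arithmetic, the signed-rank
# null by literal enumeration of all sign vectors.

itbl <- function(chrom, start, end, ...) {
  interval_tbl(chrom = chrom, start = start, end = end, ...)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  itbl(sample(chroms, n, replace = TRUE), start, start + len)
}

random_tss <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  tibble::tibble(
    gene_id = sprintf("g%03d", sample.int(999, n)),
    chrom = sample(chroms, n, replace = TRUE),
    tss = sample.int(max_pos, n, replace = TRUE) - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
}

# quadratic overlap scan: rows of `collection` sharing >= min_overlap bases
# with the probe row, by start order
brute_overlaps <- function(collection, probe, min_overlap = 1) {
  hit <- logical(nrow(collection))
  for (i in seq_len(nrow(collection))) {
    if (collection$chrom[i] != probe$chrom[1]) next
    ov <- min(collection$end[i], probe$end[1]) -
      max(collection$start[i], probe$start[1])
    hit[i] <- ov >= min_overlap
  }
  out <- collection[hit, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# exhaustive nearest-TSS scan with the documented tie-breaks: smallest
# absolute distance, then lexicographically smallest gene id
brute_nearest_tss <- function(tss, chrom, pos) {
  sub <- tss[tss$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0) return(list(gene = NA_character_, dist = NA_integer_))
  d <- pos - sub$tss
  cand <- which(abs(d) == min(abs(d)))
  cand <- cand[order(sub$gene_id[cand])][1]
  signed <- d[cand]
  if (sub$strand[cand] == "-") signed <- -signed
  list(gene = sub$gene_id[cand], dist = as.integer(signed))
}

# literal enumeration of all 2^n sign assignments for the signed-rank test
brute_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9))
  min(1, p)
}

# deterministic coverage track with Gaussian bumps at the given centers
bump_track <- function(chrom_len, centers, amplitude = 100, sd = 75,
                       bin_width = 10, background = 0, label = "bumps") {
  nb <- ceiling(chrom_len / bin_width)
  x <- (seq_len(nb) - 1) * bin_width + bin_width / 2
  sig <- rep(background, nb)
  for (cc in centers) sig <- sig + amplitude * exp(-(x - cc)^2 / (2 * sd^2))
  coverage_track(list(chr1 = sig), bin_width = bin_width, label = label)
}

tiny_config <- function(seed = 1, n_genes = 100, n_peaks = 200, ...) {
  synthetic_config(seed = seed, n_genes = n_genes, n_peaks = n_peaks, ...)
}
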