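# +1/-1 nucleosome spacing around TSSs from an acetylation coverage track.
# Coverage lives in fixed-width bins per chromosome; the caller smooths the
# signal around each TSS and takes the highest sufficiently prominent local
# maximum strictly downstream (+1) and strictly upstream (-1) of the TSS on
# the strand-oriented axis.

#' Construct a binned coverage track
#'
#' @param signal Named list (one numeric vector per chromosome) of
#'   non-negative per-bin signal.
#' @param bin_width Bin width in bases.
#' @param label Optional track label.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(signal, bin_width = 10L, label = NULL) {
  if (any(vapply(signal, function(s) any(s < 0), logical(1)))) {
    abort("coverage signal must be non-negative")
  }
  out <- list(signal = signal, bin_width = as.integer(bin_width),
              label = label)
  class(out) <- "coverage_track"
  out
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("Coverage track '%s': %d chromosome(s), bin width %d bp\n",
              x$label %||% "", length(x$signal), x$bin_width))
  invisible(x)
}

#' Read a bedGraph file into a binned coverage track
#'
#' Four-column bedGraph (chrom, start, end, value; 0-based half-open).
#' Records may arrive unsorted but must not overlap; the signal is
#' rasterized to fixed-width bins as the length-weighted mean per bin, with
#' uncovered bases contributing zero.
#'
#' @param path Input path.
#' @param bin_width Raster bin width in bases (default 10).
#' @param genome Optional named chromosome-length vector (otherwise the
#'   maximum record end per chromosome is used).
#' @param label Optional track label.
#' @return A `coverage_track` object.
#' @export
read_bedgraph <- function(path, bin_width = 10L, genome = NULL,
                          label = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  df <- df[!grepl("^track", df$chrom), , drop = FALSE]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$value <- as.numeric(df$value)
  if (any(df$value < 0)) abort(paste0(path, ": negative coverage values"))
  if (any(df$start < 0 | df$start >= df$end)) {
    abort(paste0(path, ": invalid bedGraph coordinates"))
  }
  df <- arrange(df, .data$chrom, .data$start)
  signal <- list()
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      abort(paste0(path, ": overlapping bedGraph records on ", chr))
    }
    len <- if (!is.null(genome) && chr %in% names(genome)) genome[[chr]] else
      max(sub$end)
    signal[[chr]] <- rasterize_records(sub$start, sub$end, sub$value,
                                       len, bin_width)
  }
  coverage_track(signal, bin_width = bin_width,
                 label = label %||% basename(path))
}

# length-weighted mass accumulation into fixed-width bins, then mass / width
rasterize_records <- function(start, end, value, chrom_len, bw) {
  nbins <- ceiling(chrom_len / bw)
  mass <- numeric(nbins)
  k0 <- start %/% bw            # 0-based first bin
  k1 <- (end - 1L) %/% bw       # 0-based last bin
  first_end <- pmin(end, (k0 + 1L) * bw)
  w_first <- value * (first_end - start)
  mass_add <- rowsum(w_first, k0 + 1L)
  mass[as.integer(rownames(mass_add))] <-
    mass[as.integer(rownames(mass_add))] + mass_add[, 1]
  multi <- which(k1 > k0)
  if (length(multi) > 0) {
    w_last <- value[multi] * (end[multi] - k1[multi] * bw)
    mass_add <- rowsum(w_last, k1[multi] + 1L)
    mass[as.integer(rownames(mass_add))] <-
      mass[as.integer(rownames(mass_add))] + mass_add[, 1]
    # interior bins carry value * bw each; accumulate with a difference array
    interior <- which(k1 > k0 + 1L)
    if (length(interior) > 0) {
      incr <- numeric(nbins + 1L)
      lo <- k0[interior] + 2L; hi <- k1[interior]  # 1-based inclusive range
      add <- rowsum(value[interior] * bw, lo)
      incr[as.integer(rownames(add))] <- incr[as.integer(rownames(add))] + add[, 1]
      sub <- rowsum(value[interior] * bw, hi + 1L)
      incr[as.integer(rownames(sub))] <- incr[as.integer(rownames(sub))] - sub[, 1]
      mass <- mass + cumsum(incr)[seq_len(nbins)]
    }
  }
  mass / bw
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bins are merged into single records; zero runs are
#' omitted.
#'
#' @param track A `coverage_track` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  bw <- track$bin_width
  parts <- lapply(names(track$signal), function(chr) {
    r <- rle(track$signal[[chr]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    data.frame(chrom = chr, start = starts[keep] * bw, end = ends[keep] * bw,
               value = signif(r$values[keep], 8))
  })
  readr::write_tsv(do.call(rbind, parts), path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

# moving-average smoothing with edge replication; w forced odd
smooth_ma <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(x)
  h <- (w - 1L) %/% 2L
  padded <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))[
    seq_along(x) + h]
}

# indices of strict-rise local maxima (first bin of a plateau)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Call the +1 and -1 nucleosomes flanking each TSS
#'
#' The coverage around each TSS (`tss - search` to `tss + search`) is
#' smoothed with a moving average of width `smooth_bandwidth` bases. On the
#' strand-oriented axis, the +1 nucleosome is the highest local maximum
#' strictly downstream of the TSS and the -1 nucleosome the highest strictly
#' upstream; a side with no local maximum reaching
#' `min_prominence * max(window)` yields no call for that gene.
#'
#' @param track A `coverage_track` (e.g. H3K27Ac coverage).
#' @param tss TSS tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param search Half-window in bases around the TSS (default 1000).
#' @param smooth_bandwidth Moving-average width in bases (default 50).
#' @param min_prominence Minimum peak height as a fraction of the window
#'   maximum (default 0.1).
#' @return A tibble with one row per gene: `gene_id`, `strand`, `minus1`,
#'   `plus1` (genome coordinates of the called dyads), `distance`
#'   (strand-oriented +1 minus -1 position, > 0), `prom_minus`, `prom_plus`,
#'   `status` (`"ok"` or `"no_call"`), `reason`.
#' @export
call_flanking_nucleosomes <- function(track, tss, search = 1000L,
                                      smooth_bandwidth = 50L,
                                      min_prominence = 0.1) {
  bw <- track$bin_width
  nb <- as.integer(search %/% bw)
  w_bins <- max(1L, round(smooth_bandwidth / bw))
  n <- nrow(tss)
  res <- tibble(gene_id = tss$gene_id, strand = tss$strand,
                minus1 = NA_real_, plus1 = NA_real_, distance = NA_real_,
                prom_minus = NA_real_, prom_plus = NA_real_,
                status = "no_call", reason = NA_character_)
  for (i in seq_len(n)) {
    sig <- track$signal[[tss$chrom[i]]]
    if (is.null(sig)) { res$reason[i] <- "chromosome absent"; next }
    k_tss <- tss$tss[i] %/% bw + 1L
    lo <- k_tss - nb; hi <- k_tss + nb
    if (lo < 1L || hi > length(sig)) {
      res$reason[i] <- "window outside chromosome"; next
    }
    win <- smooth_ma(sig[lo:hi], w_bins)
    wmax <- max(win)
    if (wmax <= 0) { res$reason[i] <- "flat window"; next }
    maxima <- local_maxima(win)
    center <- nb + 1L
    right <- maxima[maxima > center]
    left <- maxima[maxima < center]
    if (tss$strand[i] == "-") { tmp <- right; right <- left; left <- tmp }
    # right = downstream (+1) side, left = upstream (-1) side
    pick <- function(cand) {
      cand <- cand[win[cand] >= min_prominence * wmax]
      if (length(cand) == 0) return(NA_integer_)
      cand[which.max(win[cand])]
    }
    i_plus <- pick(right); i_minus <- pick(left)
    if (is.na(i_plus) || is.na(i_minus)) {
      res$reason[i] <- "no prominent flanking maximum"; next
    }
    pos <- function(k) (lo + k - 2L) * bw + bw / 2  # genome coord of bin center
    p_plus <- pos(i_plus); p_minus <- pos(i_minus)
    res$plus1[i] <- p_plus
    res$minus1[i] <- p_minus
    res$distance[i] <- abs(p_plus - p_minus)
    res$prom_plus[i] <- win[i_plus] / wmax
    res$prom_minus[i] <- win[i_minus] / wmax
    res$status[i] <- "ok"
  }
  res
}

#' Compare +1/-1 nucleosome spacing between two conditions
#'
#' Restricts both call sets to the genes called in *both* conditions, reports
#' each condition's median spacing over that intersection, and tests the
#' paired per-gene spacing differences with the Wilcoxon signed-rank test
#' ([wilcoxon_signed_rank()]).
#'
#' @param calls_a,calls_b Call tibbles from [call_flanking_nucleosomes()].
#' @param label_a,label_b Condition labels for reporting.
#' @param mode Wilcoxon mode, see [wilcoxon_signed_rank()].
#' @param min_pairs Minimum number of paired genes (default 6).
#' @return A `spacing_comparison` object: list with `label_a`, `label_b`,
#'   `median_a`, `median_b`, `n_pairs`, `test` (a `wsr_test`), `pairs`
#'   (per-gene tibble).
#' @export
compare_spacing <- function(calls_a, calls_b, label_a = "A", label_b = "B",
                            mode = "auto", min_pairs = 6L) {
  a <- calls_a[calls_a$status == "ok", c("gene_id", "distance")]
  b <- calls_b[calls_b$status == "ok", c("gene_id", "distance")]
  pairs <- inner_join(a, b, by = "gene_id", suffix = c("_a", "_b"))
  if (nrow(pairs) < min_pairs) {
    abort(sprintf("only %d genes called in both conditions (need >= %d)",
                  nrow(pairs), min_pairs))
  }
  test <- wilcoxon_signed_rank(pairs$distance_a - pairs$distance_b,
                               mode = mode)
  out <- list(label_a = label_a, label_b = label_b,
              median_a = median(pairs$distance_a),
              median_b = median(pairs$distance_b),
              n_pairs = nrow(pairs), test = test, pairs = pairs)
  class(out) <- "spacing_comparison"
  out
}

#' @export
print.spacing_comparison <- function(x, ...) {
  cat(sprintf("+1/-1 nucleosome spacing: %s vs %s over %d paired genes\n",
              x$label_a, x$label_b, x$n_pairs))
  cat(sprintf("  median %s = %g bp, median %s = %g bp\n",
              x$label_a, x$median_a, x$label_b, x$median_b))
  cat(sprintf("  paired Wilcoxon (%s): W = %g, p = %.4g\n",
              x$test$method, x$test$statistic, x$test$p_value))
  invisible(x)
}

#' @export
tidy.spacing_comparison <- function(x, ...) {
  mutate(x$pairs, difference = .data$distance_a - .data$distance_b)
}

#' @export
glance.spacing_comparison <- function(x, ...) {
  tibble(label_a = x$label_a, label_b = x$label_b,
         median_a = x$median_a, median_b = x$median_b,
         n_pairs = x$n_pairs, statistic = x$test$statistic,
         p.value = x$test$p_value, method = x$test$method)
}
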