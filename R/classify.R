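# Chromatin-state classification of factor peaks against histone-mark peak
# sets. Proximal peaks (within `proximal_bp` of a TSS) are labeled
# active / bivalent / other from H3K4me3 + H3K27Ac / H3K27me3 co-occurrence;
# distal peaks fall through a priority cascade over H3K4me1 / H3K27Ac /
# H3K27me3 into bivalent > active > repressed > latent > isolated, with an
# `other` bucket for the combination (H3K27Ac alone) that none of the named
# classes covers.

proximal_labels <- c("active", "bivalent", "other")
distal_labels <- c("active", "bivalent", "isolated", "latent", "repressed",
                   "other")

#' Split peaks into promoter-proximal and promoter-distal
#'
#' A peak is promoter-proximal when the absolute signed distance from its
#' anchor (summit when available, else midpoint) to the nearest TSS is at
#' most `threshold` bases; all other peaks are promoter-distal. The split is
#' exhaustive and exclusive.
#'
#' @param peaks Interval tibble (see [interval_tbl()]).
#' @param tss TSS tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param threshold Proximity cutoff in bases (default 1000).
#' @param anchor Passed to [interval_anchor()].
#' @return `peaks` with added columns `anchor_pos`, `nearest_gene`,
#'   `tss_distance`, `locality` (`"proximal"` / `"distal"`).
#' @export
split_proximal_distal <- function(peaks, tss, threshold = 1000L,
                                  anchor = c("summit", "midpoint")) {
  if (nrow(peaks) == 0) {
    warn("empty peak set")
    peaks$anchor_pos <- integer()
    peaks$nearest_gene <- character()
    peaks$tss_distance <- integer()
    peaks$locality <- character()
    return(peaks)
  }
  out <- distance_to_nearest_tss(peaks, tss, anchor = anchor)
  out$locality <- ifelse(!is.na(out$tss_distance) &
                           abs(out$tss_distance) <= threshold,
                         "proximal", "distal")
  out
}

#' Classify promoter-proximal peaks from histone-mark overlap
#'
#' A proximal peak is *active* when it overlaps both an H3K4me3 and an
#' H3K27Ac peak, and *bivalent* when it overlaps both an H3K4me3 and an
#' H3K27me3 peak. A peak satisfying both rules carries the label `bivalent`
#' but both rule flags, so composition tallies can mirror the non-additive
#' active/bivalent rates seen in promoter classification. Peaks satisfying
#' neither rule are `other`.
#'
#' @param peaks Interval tibble of proximal peaks.
#' @param k4me3,k27ac,k27me3 Mark peak interval tibbles (may be empty).
#' @param min_overlap Minimum shared bases for a mark overlap (default 1).
#' @return A tibble with one row per peak: `category`, `rule_active`,
#'   `rule_bivalent`.
#' @export
classify_proximal <- function(peaks, k4me3, k27ac, k27me3, min_overlap = 1L) {
  has_k4me3 <- overlaps_any(peaks, k4me3, min_overlap)
  has_k27ac <- overlaps_any(peaks, k27ac, min_overlap)
  has_k27me3 <- overlaps_any(peaks, k27me3, min_overlap)
  rule_active <- has_k4me3 & has_k27ac
  rule_bivalent <- has_k4me3 & has_k27me3
  category <- ifelse(rule_bivalent, "bivalent",
                     ifelse(rule_active, "active", "other"))
  tibble(category = category, rule_active = rule_active,
         rule_bivalent = rule_bivalent)
}

#' Classify promoter-distal peaks from histone-mark overlap
#'
#' Priority cascade over overlap with H3K4me1, H3K27Ac and H3K27me3 peaks:
#' *bivalent* (all three marks) > *active* (H3K27Ac and H3K4me1) >
#' *repressed* (H3K27me3) > *latent* (H3K4me1 only) > *isolated* (none of
#' the three). The one remaining combination, H3K27Ac alone, is reported as
#' `other` by default; `strict_five = TRUE` folds it into `latent` so the
#' five named classes partition the distal peaks.
#'
#' @param peaks Interval tibble of distal peaks.
#' @param k4me1,k27ac,k27me3 Mark peak interval tibbles.
#' @param min_overlap Minimum shared bases for a mark overlap.
#' @param strict_five Fold the `other` bucket into `latent`.
#' @return A tibble with one row per peak: `category` and the three overlap
#'   flags `has_k4me1`, `has_k27ac`, `has_k27me3`.
#' @export
classify_distal <- function(peaks, k4me1, k27ac, k27me3, min_overlap = 1L,
                            strict_five = FALSE) {
  has_k4me1 <- overlaps_any(peaks, k4me1, min_overlap)
  has_k27ac <- overlaps_any(peaks, k27ac, min_overlap)
  has_k27me3 <- overlaps_any(peaks, k27me3, min_overlap)
  category <- dplyr::case_when(
    has_k27me3 & has_k27ac & has_k4me1 ~ "bivalent",
    has_k27ac & has_k4me1 ~ "active",
    has_k27me3 ~ "repressed",
    has_k4me1 ~ "latent",
    !has_k4me1 & !has_k27ac & !has_k27me3 ~ "isolated",
    TRUE ~ "other"  # H3K27Ac alone
  )
  if (strict_five) category[category == "other"] <- "latent"
  tibble(category = category, has_k4me1 = has_k4me1,
         has_k27ac = has_k27ac, has_k27me3 = has_k27me3)
}

#' Classify a factor peak set into seven chromatin-state categories
#'
#' Runs the proximal/distal split then [classify_proximal()] and
#' [classify_distal()] on the respective subsets. The returned tibble keeps
#' one row per input peak with its locality, category, nearest gene and
#' signed TSS distance.
#'
#' @param peaks Factor peak interval tibble.
#' @param tss TSS tibble.
#' @param k4me3,k4me1,k27ac,k27me3 Histone-mark peak interval tibbles.
#' @param proximal_bp Promoter-proximal cutoff in bases.
#' @param min_overlap Minimum shared bases for a mark overlap.
#' @param strict_five See [classify_distal()].
#' @param anchor Passed to [interval_anchor()].
#' @return A `classified_peaks` tibble: the peak columns plus `locality`,
#'   `category` (e.g. `"proximal_active"`, `"distal_latent"`),
#'   `nearest_gene`, `tss_distance`, and the proximal rule flags.
#' @export
classify_peaks <- function(peaks, tss, k4me3, k4me1, k27ac, k27me3,
                           proximal_bp = 1000L, min_overlap = 1L,
                           strict_five = FALSE,
                           anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  out <- split_proximal_distal(peaks, tss, threshold = proximal_bp,
                               anchor = anchor)
  out$category <- NA_character_
  out$rule_active <- NA
  out$rule_bivalent <- NA
  is_prox <- out$locality == "proximal"
  if (any(is_prox)) {
    sub <- classify_proximal(out[is_prox, , drop = FALSE], k4me3, k27ac,
                             k27me3, min_overlap)
    out$category[is_prox] <- paste0("proximal_", sub$category)
    out$rule_active[is_prox] <- sub$rule_active
    out$rule_bivalent[is_prox] <- sub$rule_bivalent
  }
  if (any(!is_prox)) {
    sub <- classify_distal(out[!is_prox, , drop = FALSE], k4me1, k27ac,
                           k27me3, min_overlap, strict_five = strict_five)
    out$category[!is_prox] <- paste0("distal_", sub$category)
  }
  class(out) <- c("classified_peaks", class(out))
  attr(out, "proximal_bp") <- proximal_bp
  attr(out, "strict_five") <- strict_five
  out
}

#' Category composition of a classified peak set
#'
#' Counts and fractions per chromatin-state category. `mode = "label"`
#' (default) tallies the exclusive labels, so counts sum to the number of
#' peaks. `mode = "rule"` tallies proximal peaks by the classification
#' *rules* instead: a peak overlapping H3K4me3 together with both H3K27Ac
#' and H3K27me3 counts toward both the active and the bivalent rate (the
#' rates need not sum to 100%); distal tallies are unchanged.
#'
#' @param classified Output of [classify_peaks()].
#' @param mode `"label"` or `"rule"`.
#' @return A tibble with `locality`, `category`, `n`, `frac_total` (fraction
#'   of all peaks) and `frac_locality` (fraction of the locality subset).
#' @export
class_composition <- function(classified, mode = c("label", "rule")) {
  mode <- match.arg(mode)
  if (nrow(classified) == 0) {
    return(tibble(locality = character(), category = character(),
                  n = integer(), frac_total = numeric(),
                  frac_locality = numeric()))
  }
  total <- nrow(classified)
  n_by_loc <- table(classified$locality)
  rows <- list()
  for (loc in c("proximal", "distal")) {
    labs <- if (loc == "proximal") proximal_labels else distal_labels
    sub <- classified[classified$locality == loc, , drop = FALSE]
    for (lab in labs) {
      full <- paste0(loc, "_", lab)
      n_lab <- if (mode == "rule" && loc == "proximal" && lab == "active") {
        sum(sub$rule_active, na.rm = TRUE)
      } else if (mode == "rule" && loc == "proximal" && lab == "bivalent") {
        sum(sub$rule_bivalent, na.rm = TRUE)
      } else {
        sum(sub$category == full)
      }
      rows[[full]] <- tibble(
        locality = loc, category = full, n = as.integer(n_lab),
        frac_total = n_lab / total,
        frac_locality = if (loc %in% names(n_by_loc) && n_by_loc[[loc]] > 0)
          n_lab / n_by_loc[[loc]] else NA_real_)
    }
  }
  bind_rows(rows)
}

#' Write classified peaks as BED6 with the category in the name field
#'
#' @param classified Output of [classify_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classified_bed <- function(classified, path) {
  x <- classified
  x$name <- paste0(x$name, "|", x$category)
  write_bed(x, path)
}

#' Peak-centered signal matrix
#'
#' Mean coverage per bin over a fixed window `[center - flank, center +
#' flank)` around each peak center, from a binned coverage track (see
#' [read_bedgraph()]). Bins that fall outside the covered chromosome extent
#' are set to `NA`, as are whole rows for peaks on chromosomes absent from
#' the track.
#'
#' @param peaks Interval tibble; the window is centered on each peak's
#'   midpoint.
#' @param track A `coverage_track` object.
#' @param flank Half-window size in bases (default 10000).
#' @param bins Number of equal-width bins across the window.
#' @return A numeric matrix (peaks x bins) with peak names as row names and
#'   bin-center offsets (bases relative to the peak center) as an attribute
#'   `bin_mids`.
#' @export
peak_signal_matrix <- function(peaks, track, flank = 10000L, bins = 100L) {
  stopifnot(inherits(track, "coverage_track"))
  if (bins < 1) abort("bins must be >= 1")
  bw <- track$bin_width
  win <- 2 * flank
  bases_per_bin <- win / bins
  centers <- peaks$start + (peaks$end - peaks$start) %/% 2L
  out <- matrix(NA_real_, nrow = nrow(peaks), ncol = bins,
                dimnames = list(peaks$name, NULL))
  # per-base positions are aggregated track-bin-first: value at base b is the
  # track bin floor(b / bw); each output bin averages its bases_per_bin bases
  for (i in seq_len(nrow(peaks))) {
    sig <- track$signal[[peaks$chrom[i]]]
    if (is.null(sig)) {
      warn(sprintf("chromosome %s absent from track '%s'", peaks$chrom[i],
                   track$label %||% ""))
      next
    }
    chrom_len <- length(sig) * bw
    w_start <- centers[i] - flank
    edges <- w_start + round(seq(0, win, length.out = bins + 1))
    for (j in seq_len(bins)) {
      b0 <- edges[j]; b1 <- edges[j + 1]
      if (b0 < 0 || b1 > chrom_len) next  # NA: window truncated by the edge
      k0 <- floor(b0 / bw) + 1
      k1 <- ceiling(b1 / bw)
      piece <- sig[k0:k1]
      # length-weighted mean over partially covered track bins
      wts <- pmin((k0:k1) * bw, b1) - pmax(((k0:k1) - 1) * bw, b0)
      out[i, j] <- sum(piece * wts) / sum(wts)
    }
  }
  attr(out, "bin_mids") <- -flank + (seq_len(bins) - 0.5) * bases_per_bin
  attr(out, "flank") <- flank
  out
}
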