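# Cross-tissue peak-set comparison: asymmetric overlap fractions and a
# symmetric Pearson correlation of binary membership over the merged union
# of all sets' peaks.

#' Fraction of one peak set overlapping another
#'
#' `overlap_fraction(a, b)` is the fraction of peaks in `a` sharing at least
#' `min_overlap` bases with any peak in `b` — asymmetric by definition.
#'
#' @param a,b Interval tibbles.
#' @param min_overlap Minimum shared bases.
#' @return A fraction in \[0, 1\], or `NA` with a warning when `a` is empty.
#' @export
overlap_fraction <- function(a, b, min_overlap = 1L) {
  if (nrow(a) == 0) {
    warn("overlap fraction undefined for an empty query set")
    return(NA_real_)
  }
  mean(overlaps_any(a, b, min_overlap))
}

#' Pairwise overlap and correlation matrices across peak sets
#'
#' For every ordered pair of sets the asymmetric overlap fraction (row set
#' against column set) is computed; additionally, all sets' peaks are merged
#' into a union atlas of disjoint regions and each set is encoded as a binary
#' membership vector over the atlas, whose Pearson correlations give a
#' symmetric similarity matrix. Optionally the sets are first classified
#' against a shared TSS table and restricted to proximal or distal peaks.
#'
#' @param sets Named list of interval tibbles (>= 2).
#' @param min_overlap Minimum shared bases for an overlap.
#' @param locality `"all"`, `"proximal"` or `"distal"`; filtering requires
#'   `tss`.
#' @param tss TSS tibble, required when `locality != "all"`.
#' @param proximal_bp Proximity cutoff used for the locality filter.
#' @return An `overlap_matrix` object: list with `labels`, `fraction`
#'   (square matrix, row-vs-column overlap fractions), `correlation`
#'   (symmetric membership correlation), `n_union` (atlas size).
#' @export
overlap_matrix <- function(sets, min_overlap = 1L,
                           locality = c("all", "proximal", "distal"),
                           tss = NULL, proximal_bp = 1000L) {
  locality <- match.arg(locality)
  if (length(sets) < 2) abort("need at least 2 peak sets")
  labels <- names(sets) %||% paste0("set_", seq_along(sets))
  if (is.null(names(sets))) names(sets) <- labels
  if (locality != "all") {
    if (is.null(tss)) abort("locality filtering requires a TSS table")
    sets <- lapply(sets, function(s) {
      s <- split_proximal_distal(s, tss, threshold = proximal_bp)
      s[s$locality == locality, , drop = FALSE]
    })
  }
  k <- length(sets)
  frac <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      frac[i, j] <- if (i == j && nrow(sets[[i]]) > 0) 1 else
        overlap_fraction(sets[[i]], sets[[j]], min_overlap)
    }
  }
  union_gr <- GenomicRanges::reduce(do.call(
    c, lapply(unname(sets), intervals_to_granges)))
  atlas <- tibble(chrom = as.character(GenomicRanges::seqnames(union_gr)),
                  start = GenomicRanges::start(union_gr) - 1L,
                  end = GenomicRanges::end(union_gr),
                  name = paste0("u", seq_along(union_gr)),
                  score = NA_real_, strand = ".",
                  summit_offset = NA_integer_)
  membership <- matrix(NA_real_, nrow = nrow(atlas), ncol = k)
  for (j in seq_len(k)) {
    membership[, j] <- as.numeric(overlaps_any(atlas, sets[[j]], min_overlap))
  }
  correlation <- suppressWarnings(cor(membership))
  # Pearson is undefined for a constant membership vector (a set covering
  # every union region, or none): identical patterns count as 1, else 0
  for (idx in which(is.na(correlation))) {
    i <- (idx - 1) %% k + 1; j <- (idx - 1) %/% k + 1
    correlation[idx] <- as.numeric(all(membership[, i] == membership[, j]))
  }
  diag(correlation) <- 1
  dimnames(correlation) <- list(labels, labels)
  out <- list(labels = labels, fraction = frac, correlation = correlation,
              n_union = nrow(atlas), locality = locality)
  class(out) <- "overlap_matrix"
  out
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("Cross-set overlap matrix: %d sets, %d union regions (%s)\n",
              length(x$labels), x$n_union, x$locality))
  cat("Overlap fractions (row set vs column set):\n")
  print(round(x$fraction, 3))
  invisible(x)
}

#' @export
tidy.overlap_matrix <- function(x, ...) {
  k <- length(x$labels)
  grid <- expand.grid(set_a = x$labels, set_b = x$labels,
                      stringsAsFactors = FALSE)
  tibble(set_a = grid$set_a, set_b = grid$set_b,
         overlap_fraction = as.vector(x$fraction),
         membership_correlation = as.vector(x$correlation))
}

#' Heat map of a cross-set overlap or correlation matrix
#'
#' @param object An `overlap_matrix` object.
#' @param statistic `"fraction"` or `"correlation"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_matrix <- function(object, statistic = c("fraction",
                                                          "correlation"),
                                    ...) {
  statistic <- match.arg(statistic)
  df <- tidy(object)
  df$value <- if (statistic == "fraction") df$overlap_fraction else
    df$membership_correlation
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_b, y = .data$set_a,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(0, min(df$value)), 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = statistic,
                  title = sprintf("Peak-set %s (%s peaks)", statistic,
                                  object$locality)) +
    ggplot2::theme_minimal()
}
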