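# Genomic interval data model: peaks and annotation features live in tibbles
# with columns chrom / start / end (0-based, half-open) plus optional name,
# score, strand and summit_offset (narrowPeak column 10). All downstream
# overlap queries run on GenomicRanges built from these tibbles.

interval_cols <- c("chrom", "start", "end", "name", "score", "strand",
                   "summit_offset")

#' Construct a peak/interval tibble
#'
#' Builds a sorted interval collection in the package's internal convention:
#' 0-based half-open coordinates, one row per interval. Most users will not
#' call this directly; [read_bed()] and the synthetic generators produce the
#' same shape.
#'
#' @param chrom Chromosome names.
#' @param start,end Integer coordinates, 0-based half-open (`start < end`).
#' @param name Optional interval identifiers (default `peak_1`, ...).
#' @param score Optional numeric scores.
#' @param strand `"+"`, `"-"` or `"."` (unstranded, the default).
#' @param summit_offset Optional offset of the peak summit from `start`
#'   (must satisfy `0 <= summit_offset < end - start`), `NA` if unknown.
#' @param label Optional collection label (sample or mark name), stored as an
#'   attribute.
#' @param genome Optional named vector of chromosome lengths; intervals must
#'   not extend past them.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `summit_offset`, sorted by (`chrom`, `start`, `end`).
#' @export
interval_tbl <- function(chrom, start, end, name = NULL, score = NA_real_,
                         strand = ".", summit_offset = NA_integer_,
                         label = NULL, genome = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- paste0("peak_", seq_len(n))
  x <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.numeric(score),
    strand = as.character(strand),
    summit_offset = as.integer(summit_offset)
  )
  validate_intervals(x, genome = genome)
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  attr(x, "label") <- label
  x
}

validate_intervals <- function(x, genome = NULL, context = "interval table") {
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: invalid coordinates (need 0 <= start < end) at row(s) %s",
      context, paste(head(bad, 5), collapse = ", ")))
  }
  has_summit <- !is.na(x$summit_offset)
  bad <- which(has_summit &
                 (x$summit_offset < 0 | x$summit_offset >= x$end - x$start))
  if (length(bad) > 0) {
    abort(sprintf("%s: summit_offset outside interval at row(s) %s",
                  context, paste(head(bad, 5), collapse = ", ")))
  }
  if (!is.null(genome)) {
    len <- genome[x$chrom]
    bad <- which(!is.na(len) & x$end > len)
    if (length(bad) > 0) {
      abort(sprintf("%s: interval extends past chromosome length at row(s) %s",
                    context, paste(head(bad, 5), collapse = ", ")))
    }
    missing_chrom <- setdiff(unique(x$chrom), names(genome))
    if (length(missing_chrom) > 0) {
      abort(sprintf("%s: chromosome(s) absent from genome: %s",
                    context, paste(missing_chrom, collapse = ", ")))
    }
  }
  invisible(x)
}

# 0-based half-open tibble -> 1-based closed GRanges
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = "*"
  )
}

#' Anchor position of each interval
#'
#' The anchor is the single base used for distance computations: the summit
#' (when `summit_offset` is present) or the interval midpoint (integer
#' division). `anchor = "midpoint"` forces the midpoint even when a summit is
#' available.
#'
#' @param x An interval tibble.
#' @param anchor `"summit"` (summit when available, else midpoint) or
#'   `"midpoint"`.
#' @return Integer vector of 0-based anchor positions.
#' @export
interval_anchor <- function(x, anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  mid <- x$start + (x$end - x$start) %/% 2L
  if (anchor == "midpoint") return(mid)
  ifelse(is.na(x$summit_offset), mid, x$start + x$summit_offset)
}

#' Read peak calls from a BED-family file
#'
#' Supports BED3, BED6 and ENCODE narrowPeak (10 columns; column 10 is the
#' summit offset from `start`, -1 meaning "not called"). Track and comment
#' lines are skipped. Coordinates are validated line by line.
#'
#' @param path Path to a tab-separated BED-family file.
#' @param dialect `"auto"` (by column count), `"bed3"`, `"bed6"` or
#'   `"narrowPeak"`.
#' @param genome Optional named chromosome-length vector for bounds checking.
#' @param label Optional collection label stored as an attribute.
#' @return A sorted interval tibble (see [interval_tbl()]).
#' @export
read_bed <- function(path, dialect = c("auto", "bed3", "bed6", "narrowPeak"),
                     genome = NULL, label = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warn(paste0("no intervals in ", path))
    return(interval_tbl(character(), integer(), integer(), label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  want <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L,
                 auto = min(nf))
  if (dialect == "auto") {
    want <- if (want >= 10L) 10L else if (want >= 6L) 6L else 3L
  }
  short <- which(nf < want)
  if (length(short) > 0) {
    abort(sprintf("%s: expected >= %d fields at line %d",
                  path, want, lineno[short[1]]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  suppress_na <- function(x) suppressWarnings(as.integer(x))
  start <- suppress_na(col(2)); end <- suppress_na(col(3))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed coordinates at line %d (start '%s', end '%s')",
                  path, lineno[bad[1]], col(2)[bad[1]], col(3)[bad[1]]))
  }
  name <- if (want >= 6L) col(4) else paste0("peak_", seq_along(start))
  score <- if (want >= 6L) suppressWarnings(as.numeric(col(5))) else NA_real_
  strand <- if (want >= 6L) col(6) else "."
  summit <- NA_integer_
  if (want == 10L) {
    summit <- suppress_na(col(10))
    summit[!is.na(summit) & summit < 0] <- NA_integer_  # -1 = summit not called
    bad <- which(!is.na(summit) & summit >= end - start)
    if (length(bad) > 0) {
      abort(sprintf("%s: summit offset outside peak at line %d",
                    path, lineno[bad[1]]))
    }
  }
  interval_tbl(col(1), start, end, name = name, score = score,
               strand = strand, summit_offset = summit,
               label = label %||% basename(path), genome = genome)
}

#' Write an interval tibble as BED6
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  out <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = ifelse(is.na(x$name), ".", x$name),
    score = ifelse(is.na(x$score), 0, x$score),
    strand = ifelse(is.na(x$strand) | x$strand == "", ".", x$strand)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a transcription start site table
#'
#' Two formats are supported. `"tsv"` is a four-column table
#' (`gene_id`, `chrom`, `tss`, `strand`) with 0-based TSS positions and an
#' optional header. `"gtf_lite"` is a 9-column GTF-style table whose
#' `transcript` rows are used; GTF coordinates are 1-based closed and are
#' converted, so a minus-strand transcript spanning `[s, e]` (1-based) has
#' TSS `e - 1` in 0-based coordinates. Duplicate (gene_id, tss) pairs are
#' collapsed.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"gtf_lite"`.
#' @return A tibble with columns `gene_id`, `chrom`, `tss`, `strand`, sorted
#'   by (`chrom`, `tss`).
#' @export
read_tss <- function(path, format = c("tsv", "gtf_lite")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(paste0("no TSS records in ", path))
    return(tibble(gene_id = character(), chrom = character(),
                  tss = integer(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    if (identical(tolower(fields[[1]][1]), "gene_id")) fields <- fields[-1]
    out <- tibble(
      gene_id = vapply(fields, `[[`, character(1), 1),
      chrom = vapply(fields, `[[`, character(1), 2),
      tss = as.integer(vapply(fields, `[[`, character(1), 3)),
      strand = vapply(fields, `[[`, character(1), 4)
    )
  } else {
    keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "transcript",
                   logical(1))
    fields <- fields[keep]
    if (length(fields) == 0) {
      abort(paste0(path, ": no transcript rows in gtf_lite input"))
    }
    strand <- vapply(fields, `[[`, character(1), 7)
    start1 <- as.integer(vapply(fields, `[[`, character(1), 4))
    end1 <- as.integer(vapply(fields, `[[`, character(1), 5))
    gene_id <- vapply(fields, function(f) {
      m <- regmatches(f[9], regexec('gene_id[ ="]+([^";]+)', f[9]))[[1]]
      if (length(m) == 2) m[2] else f[9]
    }, character(1))
    out <- tibble(
      gene_id = gene_id, chrom = vapply(fields, `[[`, character(1), 1),
      tss = ifelse(strand == "-", end1 - 1L, start1 - 1L),
      strand = strand
    )
  }
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    abort(sprintf("%s: missing/invalid strand ('%s') in TSS record %d",
                  path, out$strand[bad[1]], bad[1]))
  }
  if (any(is.na(out$tss) | out$tss < 0)) abort(paste0(path, ": invalid TSS position"))
  out |>
    distinct(.data$gene_id, .data$tss, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$tss)
}

#' Write a TSS table as TSV
#'
#' @param tss TSS tibble (`gene_id`, `chrom`, `tss`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss <- function(tss, path) {
  readr::write_tsv(tss[, c("gene_id", "chrom", "tss", "strand")], path,
                   progress = FALSE)
  invisible(path)
}

#' Intervals of a collection overlapping a probe
#'
#' Returns the members of `collection` sharing at least `min_overlap` bases
#' with the probe interval, ordered by start position.
#'
#' @param collection Interval tibble.
#' @param probe A one-row interval tibble or a list/data frame with `chrom`,
#'   `start`, `end`.
#' @param min_overlap Minimum shared bases (>= 1).
#' @return The overlapping rows of `collection`.
#' @export
query_overlaps <- function(collection, probe, min_overlap = 1L) {
  if (min_overlap < 1) abort("min_overlap must be >= 1")
  same <- collection$chrom == probe$chrom[[1]]
  ov <- pmin(collection$end, probe$end[[1]]) -
    pmax(collection$start, probe$start[[1]])
  hit <- same & ov >= min_overlap
  arrange(collection[hit, , drop = FALSE], .data$start)
}

# row index in `b` overlapped by each row of `a` (>= min_overlap shared bases);
# returns a two-column tibble of indices (a_idx, b_idx).
overlap_pairs <- function(a, b, min_overlap = 1L) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(a_idx = integer(), b_idx = integer()))
  }
  # disjoint seqlevels between the two sets are legitimate (e.g. sets on
  # different chromosomes); silence the GenomeInfoDb merge note
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    intervals_to_granges(a), intervals_to_granges(b),
    minoverlap = as.integer(min_overlap), ignore.strand = TRUE))
  tibble(a_idx = S4Vectors::queryHits(hits), b_idx = S4Vectors::subjectHits(hits))
}

# logical: does each row of `a` overlap anything in `b`
overlaps_any <- function(a, b, min_overlap = 1L) {
  out <- rep(FALSE, nrow(a))
  out[unique(overlap_pairs(a, b, min_overlap)$a_idx)] <- TRUE
  out
}

#' Signed distance from peak anchors to the nearest TSS
#'
#' For every peak the nearest TSS is found (ties broken by smaller absolute
#' distance, then lexicographic gene id) and the distance reported on the
#' gene's strand-oriented axis: positive values lie downstream of the TSS,
#' negative upstream. Peaks on chromosomes with no TSS get `NA` (unassigned).
#'
#' @param peaks Interval tibble.
#' @param tss TSS tibble.
#' @param anchor Passed to [interval_anchor()].
#' @return `peaks` with added columns `anchor_pos`, `nearest_gene`,
#'   `tss_distance`.
#' @export
distance_to_nearest_tss <- function(peaks, tss,
                                    anchor = c("summit", "midpoint")) {
  anchor <- match.arg(anchor)
  if (nrow(tss) == 0) abort("TSS table is empty")
  pos <- interval_anchor(peaks, anchor)
  nearest_gene <- rep(NA_character_, nrow(peaks))
  tss_distance <- rep(NA_integer_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    t_sub <- tss[tss$chrom == chr, , drop = FALSE]
    p_idx <- which(peaks$chrom == chr)
    if (nrow(t_sub) == 0 || length(p_idx) == 0) next
    # sorted by position then gene id, so the first record at a position is
    # the lexicographically smallest gene there
    t_sub <- t_sub[order(t_sub$tss, t_sub$gene_id), , drop = FALSE]
    u <- unique(t_sub$tss)
    first_at <- match(u, t_sub$tss)   # index of smallest gene at each position
    p <- pos[p_idx]
    i_left <- findInterval(p, u)      # last unique position <= p
    i_right <- i_left + 1L
    d_left <- ifelse(i_left >= 1, p - u[pmax(i_left, 1L)], Inf)
    d_right <- ifelse(i_right <= length(u),
                      u[pmin(i_right, length(u))] - p, Inf)
    pick <- ifelse(d_left <= d_right, first_at[pmax(i_left, 1L)],
                   first_at[pmin(i_right, length(u))])
    # equal |distance| to two different positions: lexicographic gene id
    tie <- which(is.finite(d_left) & d_left == d_right)
    for (k in tie) {
      g_l <- t_sub$gene_id[first_at[i_left[k]]]
      g_r <- t_sub$gene_id[first_at[i_right[k]]]
      pick[k] <- if (g_l <= g_r) first_at[i_left[k]] else first_at[i_right[k]]
    }
    signed <- p - t_sub$tss[pick]
    flip <- t_sub$strand[pick] == "-"
    signed[flip] <- -signed[flip]
    nearest_gene[p_idx] <- t_sub$gene_id[pick]
    tss_distance[p_idx] <- as.integer(signed)
  }
  peaks$anchor_pos <- pos
  peaks$nearest_gene <- nearest_gene
  peaks$tss_distance <- tss_distance
  peaks
}
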