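# Peak-to-gene linkage: proximal peaks link to their nearest-TSS gene,
# distal peaks link to every gene whose TSS lies within a window (default
# 100 kb, inclusive) of the peak anchor; link tables then intersect with
# differential-expression calls to yield up/down target-gene lists.

#' Link promoter-proximal peaks to their nearest gene
#'
#' @param classified Output of [classify_peaks()] (only rows with
#'   `locality == "proximal"` are used).
#' @return A tibble with `peak_name`, `gene_id`, `link_type`
#'   (`"proximal_tss"`), `distance` (signed, strand-oriented), `category`.
#' @export
link_proximal <- function(classified) {
  sub <- classified[classified$locality == "proximal", , drop = FALSE]
  tibble(peak_name = sub$name, gene_id = sub$nearest_gene,
         link_type = "proximal_tss", distance = sub$tss_distance,
         category = sub$category)
}

#' Link promoter-distal peaks to all genes within a window
#'
#' Every gene whose TSS lies within `window` bases (inclusive) of the peak
#' anchor is linked; one peak may link many genes and one gene many peaks.
#'
#' @param classified Output of [classify_peaks()] (only rows with
#'   `locality == "distal"` are used).
#' @param tss TSS tibble.
#' @param window Maximum anchor-to-TSS distance in bases (default 100000).
#' @return A tibble with `peak_name`, `gene_id`, `link_type`
#'   (`"distal_window"`), `distance` (absolute, bases), `category`.
#' @export
link_distal <- function(classified, tss, window = 100000L) {
  sub <- classified[classified$locality == "distal", , drop = FALSE]
  if (nrow(sub) == 0 || nrow(tss) == 0) {
    return(tibble(peak_name = character(), gene_id = character(),
                  link_type = character(), distance = integer(),
                  category = character()))
  }
  # windows as intervals around each anchor; a TSS point overlaps the
  # closed window [anchor - window, anchor + window]
  anchors <- sub$anchor_pos
  win_tbl <- tibble(chrom = sub$chrom,
                    start = pmax(0L, anchors - as.integer(window)),
                    end = anchors + as.integer(window) + 1L,
                    name = sub$name, score = NA_real_, strand = ".",
                    summit_offset = NA_integer_)
  tss_tbl <- tibble(chrom = tss$chrom, start = tss$tss,
                    end = tss$tss + 1L, name = tss$gene_id,
                    score = NA_real_, strand = ".",
                    summit_offset = NA_integer_)
  pairs <- overlap_pairs(win_tbl, tss_tbl)
  d <- abs(anchors[pairs$a_idx] - tss$tss[pairs$b_idx])
  keep <- d <= window   # guard against the start-clip at chromosome 0
  pairs <- pairs[keep, , drop = FALSE]
  tibble(peak_name = sub$name[pairs$a_idx],
         gene_id = tss$gene_id[pairs$b_idx],
         link_type = "distal_window",
         distance = as.integer(d[keep]),
         category = sub$category[pairs$a_idx]) |>
    arrange(.data$peak_name, .data$gene_id)
}

#' Intersect peak-gene links with differential-expression calls
#'
#' Deduplicates the linked genes and splits them by DE direction. Genes whose
#' DE calls conflict across probes cannot occur here (one row per gene in the
#' DE table), but genes linked through several peaks are counted once.
#'
#' @param links Tibble from [link_proximal()] / [link_distal()] (may be a
#'   concatenation).
#' @param de Tibble from [differential_expression()].
#' @return A `linked_de` object: list with `up` and `down` gene-id vectors,
#'   `counts` (named: n_links, n_linked_genes, n_up, n_down), and `table`
#'   (per-gene tibble with direction).
#' @export
intersect_links_with_de <- function(links, de) {
  linked_genes <- sort(unique(links$gene_id))
  if (nrow(de) > 0 && length(linked_genes) > 0 &&
      length(intersect(linked_genes, de$gene_id)) == 0) {
    abort("no overlap between linked gene ids and DE gene ids (id-space mismatch?)")
  }
  tab <- tibble(gene_id = linked_genes) |>
    inner_join(de[, c("gene_id", "log2_fc", "p_value", "fdr", "direction")],
               by = "gene_id")
  up <- tab$gene_id[tab$direction == "up"]
  down <- tab$gene_id[tab$direction == "down"]
  out <- list(
    up = up, down = down,
    counts = c(n_links = nrow(links), n_linked_genes = length(linked_genes),
               n_up = length(up), n_down = length(down)),
    table = tab)
  class(out) <- "linked_de"
  out
}

#' @export
print.linked_de <- function(x, ...) {
  cat(sprintf(
    "Peak-linked differential expression: %d links, %d genes; %d up, %d down\n",
    x$counts[["n_links"]], x$counts[["n_linked_genes"]],
    x$counts[["n_up"]], x$counts[["n_down"]]))
  invisible(x)
}

#' @export
tidy.linked_de <- function(x, ...) x$table

#' @export
glance.linked_de <- function(x, ...) {
  as_tibble(as.list(x$counts))
}
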