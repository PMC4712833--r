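# Normalized (log2, RMA-style) expression matrices: expressed-gene filtering,
# Welch-t differential expression with BH FDR, and cell-type signature
# scoring against a baseline group. Matrices travel as tibbles with a
# `gene_id` column plus one column per sample; a separate two-column tibble
# maps sample ids to group labels.

#' Read an expression matrix TSV
#'
#' Expects a header row of sample ids, a `gene_id` first column, and log2
#' scale values.
#'
#' @param path Input path.
#' @return A tibble: `gene_id` plus one numeric column per sample.
#' @export
read_expression <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1] <- "gene_id"
  if (anyDuplicated(out$gene_id)) abort(paste0(path, ": duplicate gene ids"))
  vals <- as.matrix(out[, -1])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort(paste0(path, ": non-finite or non-numeric expression values"))
  }
  out
}

#' Read a sample-to-group mapping TSV
#'
#' Two columns, `sample_id` and `group` (header optional).
#'
#' @param path Input path.
#' @return A tibble with columns `sample_id`, `group`.
#' @export
read_groups <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_names = c("sample_id", "group"), skip = 0)
  if (identical(tolower(out$sample_id[1]), "sample_id")) out <- out[-1, ]
  out
}

expr_values <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "gene_id")])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

group_samples <- function(expr, groups, group) {
  s <- groups$sample_id[groups$group == group]
  s <- intersect(s, names(expr))
  if (length(s) == 0) abort(sprintf("no samples found for group '%s'", group))
  s
}

#' Filter to genes expressed in at least one group
#'
#' Keeps a gene when its mean log2 signal within at least one group reaches
#' `min_mean_signal` (RMA-style "minimum mean signal of 6 in one class").
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param groups Sample-to-group tibble.
#' @param min_mean_signal Threshold on the within-group mean (default 6).
#' @return The filtered expression tibble.
#' @export
filter_expressed <- function(expr, groups, min_mean_signal = 6) {
  m <- expr_values(expr)
  grp <- unique(groups$group)
  if (length(grp) == 0) abort("groups table is empty")
  keep <- rep(FALSE, nrow(m))
  for (g in grp) {
    s <- group_samples(expr, groups, g)
    keep <- keep | rowMeans(m[, s, drop = FALSE]) >= min_mean_signal
  }
  expr[keep, , drop = FALSE]
}

#' Differential expression between two sample groups
#'
#' Per-gene Welch two-sample t-test on log2 values with Benjamini-Hochberg
#' adjustment across the tested genes. The log2 fold change is the group-2
#' mean minus the group-1 mean. A gene is called `up` when its fold change
#' reaches `fc_threshold` and its significance passes the chosen rule
#' (`sig_mode = "fdr"`: BH q below `fdr_threshold`; `sig_mode = "p"`: raw p
#' below `p_threshold`), `down` symmetrically, else `unchanged`.
#'
#' @param expr Expression tibble.
#' @param groups Sample-to-group tibble.
#' @param group1,group2 Group labels to compare (>= 2 samples each).
#' @param fc_threshold Fold-change cutoff on the linear scale (default 2).
#' @param p_threshold,fdr_threshold Significance cutoffs.
#' @param sig_mode `"fdr"` or `"p"`.
#' @return A tibble with `gene_id`, `log2_fc`, `t_stat`, `p_value`, `fdr`,
#'   `direction`.
#' @export
differential_expression <- function(expr, groups, group1, group2,
                                    fc_threshold = 2, p_threshold = 0.05,
                                    fdr_threshold = 0.05,
                                    sig_mode = c("fdr", "p")) {
  sig_mode <- match.arg(sig_mode)
  m <- expr_values(expr)
  s1 <- group_samples(expr, groups, group1)
  s2 <- group_samples(expr, groups, group2)
  if (length(s1) < 2 || length(s2) < 2) {
    abort("each group needs at least 2 samples")
  }
  x1 <- m[, s1, drop = FALSE]; x2 <- m[, s2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1  # zero-variance identical groups
  q <- bh_fdr(p)
  lfc <- m2 - m1
  sig <- if (sig_mode == "fdr") q < fdr_threshold else p < p_threshold
  lfc_cut <- log2(fc_threshold)
  direction <- dplyr::case_when(
    sig & lfc >= lfc_cut ~ "up",
    sig & lfc <= -lfc_cut ~ "down",
    TRUE ~ "unchanged"
  )
  tibble(gene_id = expr$gene_id, log2_fc = unname(lfc),
         t_stat = unname(tstat), p_value = unname(p), fdr = unname(q),
         direction = direction)
}

#' Read signature gene lists
#'
#' Two-column TSV (`signature`, `gene_id`); returns a tibble. A small
#' editable example ships at
#' `system.file("extdata", "signatures_example.tsv", package = "chromstate")`;
#' real signature lists are study-specific inputs.
#'
#' @param path Input path.
#' @return A tibble with columns `signature`, `gene_id`.
#' @export
read_signatures <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(out)[1:2] <- c("signature", "gene_id")
  out
}

#' Score a cell-type expression signature
#'
#' Each signature gene is z-scored against the baseline group's mean and
#' standard deviation, the per-sample score is the mean z across the
#' signature genes, and per-group mean scores are reported. By construction
#' the baseline group's mean score is (approximately) zero. Signature genes
#' absent from the matrix are skipped with a message; zero matches is an
#' error.
#'
#' @param expr Expression tibble.
#' @param groups Sample-to-group tibble.
#' @param gene_set Character vector of signature gene ids.
#' @param baseline_group Group used as the z-score reference.
#' @param signature Name of the signature (for reporting).
#' @return A `signature_score` object: list with `signature`, `samples`
#'   (tibble `sample_id`, `group`, `score`), `group_means` (tibble `group`,
#'   `score`), `n_genes`, `baseline_group`.
#' @export
signature_score <- function(expr, groups, gene_set, baseline_group,
                            signature = "signature") {
  m <- expr_values(expr)
  present <- intersect(gene_set, rownames(m))
  if (length(present) == 0) {
    abort(sprintf("no genes of signature '%s' found in the matrix", signature))
  }
  if (length(present) < length(gene_set)) {
    inform(sprintf("signature '%s': %d of %d genes absent, skipped",
                   signature, length(gene_set) - length(present),
                   length(gene_set)))
  }
  base_s <- group_samples(expr, groups, baseline_group)
  sub <- m[present, , drop = FALSE]
  mu <- rowMeans(sub[, base_s, drop = FALSE])
  sigma <- apply(sub[, base_s, drop = FALSE], 1, sd)
  sigma[sigma == 0] <- NA_real_  # constant baseline gene carries no signal
  z <- (sub - mu) / sigma
  score <- colMeans(z, na.rm = TRUE)
  samples <- tibble(sample_id = names(score), score = unname(score)) |>
    left_join(groups, by = "sample_id") |>
    select("sample_id", "group", "score")
  group_means <- samples |>
    group_by(.data$group) |>
    summarise(score = mean(.data$score), .groups = "drop")
  out <- list(signature = signature, samples = samples,
              group_means = group_means, n_genes = length(present),
              baseline_group = baseline_group)
  class(out) <- "signature_score"
  out
}

#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("Signature '%s' (%d genes, baseline = %s)\n", x$signature,
              x$n_genes, x$baseline_group))
  print(x$group_means)
  invisible(x)
}

#' @export
tidy.signature_score <- function(x, ...) {
  mutate(x$samples, signature = x$signature, .before = 1)
}

#' @export
glance.signature_score <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$group_means, names_from = "group",
                             values_from = "score")
  mutate(wide, signature = x$signature, n_genes = x$n_genes, .before = 1)
}
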