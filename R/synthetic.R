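# Ground-truth generator for every pipeline input: a toy genome with a TSS
# lattice, factor + mark peak sets with planted chromatin categories, binned
# coverage with planted +1/-1 nucleosome spacing, and expression matrices
# with planted differential expression and signature blocks. Generators are
# pure functions of the config (seed included) and deliberately share no
# overlap logic with the classifier or caller, so recovery of the planted
# truth is evidence rather than tautology.

default_composition <- c(
  proximal_active = 0.01, proximal_bivalent = 0.01,
  distal_active = 0.13, distal_bivalent = 0.01, distal_isolated = 0.61,
  distal_latent = 0.18, distal_repressed = 0.05)

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study conditions the pipeline targets: a
#' chromatin-category composition dominated by isolated distal sites, two
#' coverage conditions whose +1/-1 nucleosome spacings have medians 589 bp
#' (wild type) and 482 bp (mutant) with SD 60 bp, and a two-group microarray
#' design (4 vs 4 samples) with log2 effect size 1.5 planted on a fraction
#' of the peak-linked genes.
#'
#' @param seed Integer master seed; per-stage substreams are derived as
#'   `seed * 101 + stage offset` (genome 1, peaks 2, coverage 3,
#'   expression 4), so stages can be regenerated independently.
#' @param n_chrom Number of chromosomes.
#' @param n_genes Total gene count (split evenly across chromosomes).
#' @param gene_spacing Lattice spacing between consecutive TSSs in bases;
#'   jitter keeps all pairwise TSS distances at or above 5 kb.
#' @param n_peaks Total factor peak count.
#' @param composition Named fractions over the seven chromatin categories
#'   (must sum to 1); counts are assigned by largest-remainder rounding.
#' @param peak_width Factor peak width in bases.
#' @param spacing Named list of conditions, each `list(median=, sd=)` in
#'   bases, for the nucleosome-spacing generator.
#' @param bump_sd SD in bases of the two Gaussian coverage bumps flanking
#'   each TSS.
#' @param bump_amplitude Expected peak coverage of each bump.
#' @param coverage_background Expected background coverage within the
#'   simulated window around each TSS.
#' @param bin_width Coverage bin width in bases.
#' @param de Differential-expression model: fractions of proximally linked
#'   genes planted up/down, log2 effect size, per-sample noise SD, samples
#'   per group, baseline mean and between-gene SD of log2 expression.
#' @param signatures Named numeric vector of per-signature shifts in units
#'   of the noise SD, applied to the mutant group; each signature gets
#'   `signature_size` genes disjoint from the planted DE genes.
#' @param signature_size Genes per signature block.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chrom = 2L,
                             n_genes = 300L,
                             gene_spacing = 10000L,
                             n_peaks = 1000L,
                             composition = default_composition,
                             peak_width = 300L,
                             spacing = list(wt = list(median = 589, sd = 60),
                                            mut = list(median = 482, sd = 60)),
                             bump_sd = 75,
                             bump_amplitude = 100,
                             coverage_background = 2,
                             bin_width = 10L,
                             de = list(frac_up = 0.25, frac_down = 0.25,
                                       effect = 1.5, noise_sd = 0.3,
                                       n_per_group = 4L,
                                       baseline_mean = 7, baseline_sd = 1.2),
                             signatures = c(rod = -1, retinal_progenitor = 1,
                                            g2m = 1),
                             signature_size = 20L) {
  stopifnot(n_chrom >= 1, n_genes >= 1, n_peaks >= 1, peak_width >= 10)
  if (abs(sum(composition) - 1) > 1e-9) {
    abort("composition fractions must sum to 1")
  }
  if (any(composition < 0 | composition > 1)) {
    abort("composition fractions must lie in [0, 1]")
  }
  if (gene_spacing < 7000) {
    abort("gene_spacing must be >= 7000 so jittered TSSs stay >= 5 kb apart")
  }
  out <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              n_genes = as.integer(n_genes),
              gene_spacing = as.integer(gene_spacing),
              n_peaks = as.integer(n_peaks), composition = composition,
              peak_width = as.integer(peak_width), spacing = spacing,
              bump_sd = bump_sd, bump_amplitude = bump_amplitude,
              coverage_background = coverage_background,
              bin_width = as.integer(bin_width), de = de,
              signatures = signatures,
              signature_size = as.integer(signature_size))
  class(out) <- "synthetic_config"
  out
}

stage_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 101L + offset
}

# largest-remainder apportionment of n among the fractions
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Generate the toy genome and TSS table
#'
#' Genes are laid on a jittered lattice (spacing `gene_spacing`, jitter up to
#' 2 kb) with random strands, so all pairwise TSS distances are at least
#' 5 kb. Beyond the gene region each chromosome carries a gene-free zone in
#' which [generate_peaks()] places promoter-distal peaks.
#'
#' @param config A [synthetic_config()].
#' @return List with `genome` (named chromosome-length vector) and `tss`
#'   (tibble `gene_id`, `chrom`, `tss`, `strand`).
#' @export
generate_genome <- function(config) {
  set.seed(stage_seed(config, 1L))
  per_chrom <- largest_remainder(rep(1 / config$n_chrom, config$n_chrom),
                                 config$n_genes)
  tss_rows <- list()
  genome <- integer()
  gid <- 0L
  for (c_i in seq_len(config$n_chrom)) {
    chr <- paste0("chr", c_i)
    n_g <- per_chrom[c_i]
    base <- 10000L + (seq_len(n_g) - 1L) * config$gene_spacing
    jit <- as.integer(floor(runif(n_g, 0, 2000)))
    tss <- base + jit
    strand <- sample(c("+", "-"), n_g, replace = TRUE)
    gene_id <- sprintf("gene_%04d", gid + seq_len(n_g))
    gid <- gid + n_g
    tss_rows[[chr]] <- tibble(gene_id = gene_id, chrom = chr,
                              tss = tss, strand = strand)
    # distal zone sized for the peak budget (filled by generate_peaks)
    distal_zone <- 2000L * ceiling(config$n_peaks / config$n_chrom + 2L)
    genome[chr] <- max(tss) + 10000L + distal_zone + 10000L
  }
  list(genome = genome, tss = bind_rows(tss_rows))
}

#' Generate factor and mark peak sets with planted chromatin categories
#'
#' Category counts follow largest-remainder rounding of the configured
#' composition. Proximal-category peaks are centered within 500 bp of a
#' distinct TSS; distal-category peaks are placed on a 2 kb lattice inside
#' each chromosome's gene-free zone, at least 10 kb beyond the last TSS.
#' Histone-mark peaks are written strictly inside their factor peak's
#' footprint, in exactly the combination that makes the planted category the
#' classifier's unique answer.
#'
#' @param config A [synthetic_config()].
#' @param genome_tss Output of [generate_genome()].
#' @return List with `peaks` (factor peaks, summit at the center), `marks`
#'   (named list `k4me3`, `k4me1`, `k27ac`, `k27me3`), and `truth` (tibble
#'   `name`, `category`, `gene_id` — the planted TSS for proximal peaks,
#'   `NA` for distal).
#' @export
generate_peaks <- function(config, genome_tss) {
  set.seed(stage_seed(config, 2L))
  tss <- genome_tss$tss
  counts <- largest_remainder(config$composition, config$n_peaks)
  names(counts) <- names(config$composition)
  n_prox <- sum(counts[startsWith(names(counts), "proximal")])
  if (n_prox > nrow(tss)) {
    abort("more proximal peaks than genes; increase n_genes")
  }
  half <- config$peak_width %/% 2L
  categories <- rep(names(counts), counts)
  is_prox <- startsWith(categories, "proximal")
  centers <- integer(length(categories))
  chroms <- character(length(categories))
  gene_ids <- rep(NA_character_, length(categories))
  # proximal: one distinct gene per peak, center within +/- 500 of the TSS
  prox_idx <- which(is_prox)
  if (length(prox_idx) > 0) {
    g_pick <- sample(nrow(tss), length(prox_idx))
    centers[prox_idx] <- tss$tss[g_pick] +
      as.integer(round(runif(length(prox_idx), -500, 500)))
    chroms[prox_idx] <- tss$chrom[g_pick]
    gene_ids[prox_idx] <- tss$gene_id[g_pick]
  }
  # distal: 2 kb lattice in the gene-free zone of each chromosome
  dist_idx <- which(!is_prox)
  if (length(dist_idx) > 0) {
    chrs <- names(genome_tss$genome)
    zone_start <- vapply(chrs, function(ch) {
      max(tss$tss[tss$chrom == ch]) + 10000L
    }, integer(1))
    per_chrom <- largest_remainder(rep(1 / length(chrs), length(chrs)),
                                   length(dist_idx))
    slot_chr <- rep(chrs, per_chrom)
    slot_pos <- unlist(lapply(seq_along(chrs), function(ci) {
      zone_start[ci] + 2000L * seq_len(per_chrom[ci])
    }), use.names = FALSE)
    ord <- sample(length(dist_idx))  # decouple lattice order from category
    centers[dist_idx[ord]] <- slot_pos
    chroms[dist_idx[ord]] <- slot_chr
  }
  peaks <- interval_tbl(
    chrom = chroms, start = centers - half, end = centers + half,
    name = sprintf("peak_%05d", seq_along(categories)),
    score = round(runif(length(categories), 10, 1000), 2),
    summit_offset = half, label = "factor")
  # interval_tbl sorts; carry truth by name
  truth <- tibble(name = sprintf("peak_%05d", seq_along(categories)),
                  category = categories, gene_id = gene_ids)
  mark_for <- list(
    proximal_active = c("k4me3", "k27ac"),
    proximal_bivalent = c("k4me3", "k27me3"),
    proximal_other = character(),
    distal_active = c("k4me1", "k27ac"),
    distal_bivalent = c("k4me1", "k27ac", "k27me3"),
    distal_isolated = character(),
    distal_latent = "k4me1",
    distal_repressed = "k27me3",
    distal_other = "k27ac")
  marks <- list()
  for (mk in c("k4me3", "k4me1", "k27ac", "k27me3")) {
    sel <- vapply(categories, function(cat) mk %in% mark_for[[cat]],
                  logical(1))
    if (any(sel)) {
      marks[[mk]] <- interval_tbl(
        chrom = chroms[sel], start = centers[sel] - half + 50L,
        end = centers[sel] + half - 50L,
        name = paste0(mk, "_", seq_len(sum(sel))), label = mk)
    } else {
      marks[[mk]] <- interval_tbl(character(), integer(), integer(),
                                  label = mk)
    }
  }
  list(peaks = peaks, marks = marks, truth = truth)
}

# one truncated-normal draw per gene, lower bound 150, upper bound chosen so
# both bumps stay inside the caller's default search window
draw_spacing <- function(n, med, sd, lower = 150, upper = 1800) {
  out <- rnorm(n, med, sd)
  bad <- which(out <= lower | out >= upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), med, sd)
    bad <- which(out <= lower | out >= upper)
  }
  out
}

#' Generate per-condition coverage tracks with planted nucleosome spacing
#'
#' For every gene and condition a spacing value is drawn from a truncated
#' normal (per-condition median and SD, lower bound 150 bp) and two Gaussian
#' bumps (SD `bump_sd`) are centered `spacing / 2` bases up- and downstream
#' of the TSS. Per-bin counts are Poisson draws around the expected profile
#' plus a flat background inside the simulated window (TSS +/- 1500 bp);
#' outside the window the track is zero.
#'
#' @param config A [synthetic_config()].
#' @param genome_tss Output of [generate_genome()].
#' @return List with `tracks` (named list of `coverage_track`, one per
#'   condition) and `truth` (tibble `gene_id`, `condition`, `spacing`).
#' @export
generate_coverage <- function(config, genome_tss) {
  set.seed(stage_seed(config, 3L))
  tss <- genome_tss$tss
  bw <- config$bin_width
  win <- 1500L
  tracks <- list()
  truth <- list()
  for (cond in names(config$spacing)) {
    sp <- config$spacing[[cond]]
    spacing <- draw_spacing(nrow(tss), sp$median, sp$sd)
    signal <- lapply(genome_tss$genome, function(len) numeric(ceiling(len / bw)))
    for (i in seq_len(nrow(tss))) {
      chr <- tss$chrom[i]
      k_lo <- max(1L, (tss$tss[i] - win) %/% bw + 1L)
      k_hi <- min(length(signal[[chr]]), (tss$tss[i] + win) %/% bw + 1L)
      x <- ((k_lo:k_hi) - 1L) * bw + bw / 2   # bin centers
      mu <- config$coverage_background +
        config$bump_amplitude *
        (exp(-(x - (tss$tss[i] - spacing[i] / 2))^2 / (2 * config$bump_sd^2)) +
         exp(-(x - (tss$tss[i] + spacing[i] / 2))^2 / (2 * config$bump_sd^2)))
      signal[[chr]][k_lo:k_hi] <- rpois(length(mu), mu)
    }
    tracks[[cond]] <- coverage_track(signal, bin_width = bw, label = cond)
    truth[[cond]] <- tibble(gene_id = tss$gene_id, condition = cond,
                            spacing = spacing)
  }
  list(tracks = tracks, truth = bind_rows(truth))
}

#' Generate an expression matrix with planted DE and signature blocks
#'
#' Baseline per-gene log2 means are Normal(`baseline_mean`, `baseline_sd`)
#' (default 7 and 1.2, so most genes clear the RMA >= 6 expressed filter);
#' genes carrying planted differential expression are redrawn until their
#' baseline exceeds 6.2, so the planted truth is recoverable after the
#' expressed filter. Per-sample values add Normal(0, `noise_sd`) noise. A fraction of the
#' genes carrying a planted proximal factor peak is shifted up (or down) by
#' `effect` log2 units in the mutant group. Each configured signature gets a
#' block of genes (disjoint from the DE genes) shifted by `shift * noise_sd`
#' in the mutant group.
#'
#' @param config A [synthetic_config()].
#' @param genome_tss Output of [generate_genome()].
#' @param peak_truth `truth` tibble from [generate_peaks()].
#' @return List with `expr` (tibble `gene_id` + samples), `groups` (tibble
#'   `sample_id`, `group` with groups `WT` and `MUT`), `signatures` (tibble
#'   `signature`, `gene_id`) and `truth` (tibble `gene_id`, `direction`).
#' @export
generate_expression <- function(config, genome_tss, peak_truth) {
  set.seed(stage_seed(config, 4L))
  de <- config$de
  genes <- genome_tss$tss$gene_id
  n <- length(genes)
  linked <- sort(unique(peak_truth$gene_id[!is.na(peak_truth$gene_id)]))
  n_up <- round(de$frac_up * length(linked))
  n_down <- round(de$frac_down * length(linked))
  pick <- sample(linked, n_up + n_down)
  up_genes <- pick[seq_len(n_up)]
  down_genes <- pick[n_up + seq_len(n_down)]
  n_per <- de$n_per_group
  samples <- c(paste0("WT_", seq_len(n_per)), paste0("MUT_", seq_len(n_per)))
  groups <- tibble(sample_id = samples,
                   group = rep(c("WT", "MUT"), each = n_per))
  base <- rnorm(n, de$baseline_mean, de$baseline_sd)
  # planted differential genes must be expressed by construction (baseline
  # clear of the >= 6 filter), otherwise the planted truth is unrecoverable
  planted_idx <- match(c(up_genes, down_genes), genes)
  low <- planted_idx[base[planted_idx] < 6.2]
  while (length(low) > 0) {
    base[low] <- rnorm(length(low), de$baseline_mean, de$baseline_sd)
    low <- low[base[low] < 6.2]
  }
  m <- matrix(rnorm(n * 2 * n_per, 0, de$noise_sd), nrow = n) + base
  colnames(m) <- samples
  mut_cols <- groups$group == "MUT"
  m[match(up_genes, genes), mut_cols] <-
    m[match(up_genes, genes), mut_cols] + de$effect
  m[match(down_genes, genes), mut_cols] <-
    m[match(down_genes, genes), mut_cols] - de$effect
  # signature blocks on genes free of planted DE
  free <- setdiff(genes, c(up_genes, down_genes))
  sig_rows <- list()
  for (sig in names(config$signatures)) {
    take <- head(free, config$signature_size)
    free <- setdiff(free, take)
    if (length(take) < config$signature_size) {
      abort("not enough genes free of planted DE for the signature blocks")
    }
    m[match(take, genes), mut_cols] <-
      m[match(take, genes), mut_cols] +
      config$signatures[[sig]] * de$noise_sd
    sig_rows[[sig]] <- tibble(signature = sig, gene_id = take)
  }
  expr <- bind_cols(tibble(gene_id = genes), as_tibble(m))
  truth <- tibble(gene_id = genes,
                  direction = dplyr::case_when(
                    genes %in% up_genes ~ "up",
                    genes %in% down_genes ~ "down",
                    TRUE ~ "unchanged"))
  list(expr = expr, groups = groups, signatures = bind_rows(sig_rows),
       truth = truth)
}

#' Write a peak set as ENCODE narrowPeak
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(x, path) {
  out <- data.frame(
    chrom = x$chrom, start = x$start, end = x$end,
    name = ifelse(is.na(x$name), ".", x$name),
    score = ifelse(is.na(x$score), 0, round(x$score)),
    strand = ifelse(is.na(x$strand) | x$strand == "", ".", x$strand),
    signalValue = ifelse(is.na(x$score), 0, x$score),
    pValue = -1, qValue = -1,
    peak = ifelse(is.na(x$summit_offset), -1L, x$summit_offset))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs all generators for one config and writes every file the pipeline
#' consumes (TSS TSV, factor narrowPeak, mark BEDs, per-condition bedGraphs,
#' expression/groups/signature TSVs) plus the ground-truth tables, into
#' `dir`.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of the written file paths plus the in-memory truth
#'   tables, invisibly.
#' @export
generate_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- generate_genome(config)
  pk <- generate_peaks(config, gt)
  cv <- generate_coverage(config, gt)
  ex <- generate_expression(config, gt, pk$truth)
  paths <- list(
    tss = file.path(dir, "tss.tsv"),
    peaks = file.path(dir, "factor_peaks.narrowPeak"),
    expr = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    signatures = file.path(dir, "signatures.tsv"),
    truth_peaks = file.path(dir, "truth_peak_categories.tsv"),
    truth_spacing = file.path(dir, "truth_spacing.tsv"),
    truth_de = file.path(dir, "truth_de.tsv"))
  write_tss(gt$tss, paths$tss)
  write_narrowpeak(pk$peaks, paths$peaks)
  for (mk in names(pk$marks)) {
    paths[[mk]] <- file.path(dir, paste0(mk, ".bed"))
    write_bed(pk$marks[[mk]], paths[[mk]])
  }
  for (cond in names(cv$tracks)) {
    paths[[paste0("coverage_", cond)]] <-
      file.path(dir, paste0("coverage_", cond, ".bedgraph"))
    write_bedgraph(cv$tracks[[cond]], paths[[paste0("coverage_", cond)]])
  }
  readr::write_tsv(ex$expr, paths$expr, progress = FALSE)
  readr::write_tsv(ex$groups, paths$groups, progress = FALSE)
  readr::write_tsv(ex$signatures, paths$signatures, progress = FALSE)
  readr::write_tsv(pk$truth, paths$truth_peaks, progress = FALSE)
  readr::write_tsv(cv$truth, paths$truth_spacing, progress = FALSE)
  readr::write_tsv(ex$truth, paths$truth_de, progress = FALSE)
  genome_df <- tibble(chrom = names(gt$genome), length = unname(gt$genome))
  paths$genome <- file.path(dir, "genome.chrom.sizes")
  readr::write_tsv(genome_df, paths$genome, col_names = FALSE,
                   progress = FALSE)
  invisible(c(paths, list(truth = list(peaks = pk$truth, spacing = cv$truth,
                                       de = ex$truth))))
}
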