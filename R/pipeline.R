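# End-to-end orchestration: one configuration drives classification,
# cross-tissue comparison, differential expression, peak-gene linkage and
# nucleosome-spacing comparison, writing TSV outputs and a machine-readable
# JSON summary. The pipeline itself uses no randomness, so outputs are a
# pure function of the inputs and thresholds.

#' Build and validate a pipeline configuration
#'
#' Required inputs: the TSS table, the factor peak file and the four mark
#' peak files. Optional blocks switch on the corresponding stages: an
#' expression matrix + group table (+ two group labels) for DE and linkage
#' intersection; coverage bedGraphs for >= 2 conditions for the nucleosome
#' stage; extra peak-set paths for the cross-tissue stage.
#'
#' @param tss,peaks,k4me3,k4me1,k27ac,k27me3 Input file paths.
#' @param expr,groups Expression matrix and sample-group TSV paths
#'   (optional).
#' @param group1,group2 Group labels to compare (required with `expr`).
#' @param coverage Named character vector of bedGraph paths, one per
#'   condition; the first is the reference condition (optional).
#' @param crosstissue Named character vector of additional peak-set paths
#'   (optional; compared together with the factor peaks).
#' @param out_dir Output directory.
#' @param proximal_bp,distal_window,fc_threshold,p_threshold,fdr_threshold,
#'   min_signal,sig_mode,min_overlap,strict_five,search,smooth_bandwidth,
#'   min_prominence,wilcoxon_mode,bin_width Stage thresholds; defaults
#'   mirror the package's standard analysis (1 kb promoter window, 100 kb
#'   distal window, fold change 2, p and FDR 0.05, expressed filter 6).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(tss, peaks, k4me3, k4me1, k27ac, k27me3,
                            expr = NULL, groups = NULL,
                            group1 = NULL, group2 = NULL,
                            coverage = NULL, crosstissue = NULL,
                            out_dir = "chromstate_out",
                            proximal_bp = 1000L, distal_window = 100000L,
                            fc_threshold = 2, p_threshold = 0.05,
                            fdr_threshold = 0.05, min_signal = 6,
                            sig_mode = "p", min_overlap = 1L,
                            strict_five = FALSE, search = 1000L,
                            smooth_bandwidth = 50L, min_prominence = 0.1,
                            wilcoxon_mode = "auto", bin_width = 10L) {
  config <- list(tss = tss, peaks = peaks, k4me3 = k4me3, k4me1 = k4me1,
                 k27ac = k27ac, k27me3 = k27me3, expr = expr,
                 groups = groups, group1 = group1, group2 = group2,
                 coverage = coverage, crosstissue = crosstissue,
                 out_dir = out_dir, proximal_bp = proximal_bp,
                 distal_window = distal_window, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, fdr_threshold = fdr_threshold,
                 min_signal = min_signal, sig_mode = sig_mode,
                 min_overlap = min_overlap, strict_five = strict_five,
                 search = search, smooth_bandwidth = smooth_bandwidth,
                 min_prominence = min_prominence,
                 wilcoxon_mode = wilcoxon_mode, bin_width = bin_width)
  class(config) <- "pipeline_config"
  validate_pipeline_config(config)
}

validate_pipeline_config <- function(config) {
  stopifnot(config$proximal_bp > 0, config$distal_window > 0,
            config$fc_threshold >= 1,
            config$p_threshold > 0, config$p_threshold <= 1,
            config$fdr_threshold > 0, config$fdr_threshold <= 1)
  if (!is.null(config$expr) &&
      (is.null(config$groups) || is.null(config$group1) ||
       is.null(config$group2))) {
    abort("expression input needs groups, group1 and group2")
  }
  if (!is.null(config$coverage) && length(config$coverage) < 2) {
    abort("nucleosome stage needs coverage for >= 2 conditions")
  }
  config
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys match the arguments of [pipeline_config()]; `coverage` and
#' `crosstissue` are maps from condition/tissue name to path. Relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    out <- ifelse(grepl("^/", p), p, file.path(base, p))
    setNames(out, names(p))
  }
  for (key in c("tss", "peaks", "k4me3", "k4me1", "k27ac", "k27me3",
                "expr", "groups")) {
    raw[[key]] <- resolve(raw[[key]])
  }
  raw$coverage <- resolve(unlist(raw$coverage))
  raw$crosstissue <- resolve(unlist(raw$crosstissue))
  do.call(pipeline_config, raw)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Classification, composition, optional cross-tissue matrices, optional
#' differential expression with proximal/distal peak-gene linkage, and
#' optional nucleosome-spacing comparison. All stage outputs are written
#' under `config$out_dir` as TSV/BED plus a consolidated `summary.json`.
#'
#' @param config A `pipeline_config` (see [pipeline_config()]) or a path to
#'   a YAML file for [read_pipeline_config()].
#' @return Invisibly, a list of the in-memory stage results
#'   (`classified`, `composition`, `crosstissue`, `de`, `links`,
#'   `spacing`, `summary`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$out_dir, f)
  summary <- list(parameters = config[c(
    "proximal_bp", "distal_window", "fc_threshold", "p_threshold",
    "fdr_threshold", "min_signal", "sig_mode", "min_overlap", "strict_five",
    "search", "smooth_bandwidth", "min_prominence", "wilcoxon_mode")])
  results <- list()

  classified <- run_stage("classify", {
    tss <- read_tss(config$tss)
    peaks <- read_bed(config$peaks, label = "factor")
    marks <- lapply(config[c("k4me3", "k4me1", "k27ac", "k27me3")], read_bed)
    classify_peaks(peaks, tss, marks$k4me3, marks$k4me1, marks$k27ac,
                   marks$k27me3, proximal_bp = config$proximal_bp,
                   min_overlap = config$min_overlap,
                   strict_five = config$strict_five)
  })
  results$classified <- classified
  composition <- class_composition(classified)
  results$composition <- composition
  write_classified_bed(classified, out_path("classified_peaks.bed"))
  readr::write_tsv(composition, out_path("composition.tsv"), progress = FALSE)
  readr::write_tsv(class_composition(classified, mode = "rule"),
                   out_path("composition_rule.tsv"), progress = FALSE)
  summary$n_peaks <- nrow(classified)
  summary$n_proximal <- sum(classified$locality == "proximal")
  summary$n_distal <- sum(classified$locality == "distal")
  summary$composition <- setNames(as.list(composition$n),
                                  composition$category)

  if (!is.null(config$crosstissue)) {
    results$crosstissue <- run_stage("crosstissue", {
      tss <- read_tss(config$tss)
      sets <- c(list(factor = read_bed(config$peaks)),
                lapply(as.list(config$crosstissue), read_bed))
      lapply(setNames(c("proximal", "distal"), c("proximal", "distal")),
             function(loc) {
               om <- overlap_matrix(sets, min_overlap = config$min_overlap,
                                    locality = loc, tss = tss,
                                    proximal_bp = config$proximal_bp)
               readr::write_tsv(
                 as_tibble(om$fraction, rownames = "set"),
                 out_path(paste0("overlap_fraction_", loc, ".tsv")),
                 progress = FALSE)
               readr::write_tsv(
                 as_tibble(om$correlation, rownames = "set"),
                 out_path(paste0("overlap_correlation_", loc, ".tsv")),
                 progress = FALSE)
               om
             })
    })
  }

  if (!is.null(config$expr)) {
    de <- run_stage("differential_expression", {
      expr <- read_expression(config$expr)
      groups <- read_groups(config$groups)
      expr <- filter_expressed(expr, groups,
                               min_mean_signal = config$min_signal)
      differential_expression(expr, groups, config$group1, config$group2,
                              fc_threshold = config$fc_threshold,
                              p_threshold = config$p_threshold,
                              fdr_threshold = config$fdr_threshold,
                              sig_mode = config$sig_mode)
    })
    results$de <- de
    readr::write_tsv(de, out_path("differential_expression.tsv"),
                     progress = FALSE)
    summary$n_de_up <- sum(de$direction == "up")
    summary$n_de_down <- sum(de$direction == "down")

    links <- run_stage("linkage", {
      tss <- read_tss(config$tss)
      prox <- link_proximal(classified)
      dist <- link_distal(classified, tss, window = config$distal_window)
      list(proximal = prox, distal = dist,
           proximal_de = intersect_links_with_de(prox, de),
           distal_de = intersect_links_with_de(dist, de))
    })
    results$links <- links
    readr::write_tsv(bind_rows(links$proximal, links$distal),
                     out_path("peak_gene_links.tsv"), progress = FALSE)
    for (loc in c("proximal", "distal")) {
      ld <- links[[paste0(loc, "_de")]]
      readr::write_tsv(tibble(gene_id = ld$up),
                       out_path(paste0(loc, "_genes_up.tsv")),
                       progress = FALSE)
      readr::write_tsv(tibble(gene_id = ld$down),
                       out_path(paste0(loc, "_genes_down.tsv")),
                       progress = FALSE)
      summary[[paste0(loc, "_linked")]] <- as.list(ld$counts)
    }
  }

  if (!is.null(config$coverage)) {
    spacing <- run_stage("nucleosome_spacing", {
      tss <- read_tss(config$tss)
      tracks <- lapply(as.list(config$coverage), read_bedgraph,
                       bin_width = config$bin_width)
      calls <- lapply(tracks, call_flanking_nucleosomes, tss = tss,
                      search = config$search,
                      smooth_bandwidth = config$smooth_bandwidth,
                      min_prominence = config$min_prominence)
      ref <- names(calls)[1]
      comparisons <- lapply(names(calls)[-1], function(cond) {
        compare_spacing(calls[[ref]], calls[[cond]], label_a = ref,
                        label_b = cond, mode = config$wilcoxon_mode)
      })
      names(comparisons) <- names(calls)[-1]
      list(calls = calls, comparisons = comparisons)
    })
    results$spacing <- spacing
    for (cond in names(spacing$calls)) {
      readr::write_tsv(spacing$calls[[cond]],
                       out_path(paste0("nucleosome_calls_", cond, ".tsv")),
                       progress = FALSE)
    }
    comp_tbl <- bind_rows(lapply(spacing$comparisons, glance))
    readr::write_tsv(comp_tbl, out_path("spacing_comparison.tsv"),
                     progress = FALSE)
    summary$spacing <- lapply(spacing$comparisons, function(x) {
      list(median_a = x$median_a, median_b = x$median_b,
           n_pairs = x$n_pairs, p_value = x$test$p_value)
    })
  }

  jsonlite::write_json(summary, out_path("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  results$summary <- summary
  invisible(results)
}
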