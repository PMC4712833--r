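# chromstate

Integrative epigenomic analysis of a chromatin remodeler's ChIP-seq binding
sites, built for studies like Brg1 (Smarca4) in the developing mouse retina.
Given peak calls for the factor and four histone marks (H3K4me3, H3K4me1,
H3K27Ac, H3K27me3), a TSS annotation, normalized expression matrices and
coverage tracks, the package answers five questions in one reproducible
chain:

1. **Where does the factor bind?** Peaks are split into promoter-proximal
   (anchor within 1 kb of a TSS) and promoter-distal sites.
2. **In what chromatin state?** Proximal peaks are classified as *active*
   (H3K4me3 + H3K27Ac) or *bivalent* (H3K4me3 + H3K27me3); distal peaks
   fall through a priority cascade into *bivalent* (all three distal marks)
   > *active* (H3K27Ac + H3K4me1) > *repressed* (H3K27me3) > *latent*
   (H3K4me1 only) > *isolated* (no mark).
3. **How conserved is binding across tissues?** Pairwise overlap fractions
   and membership correlations over a merged union atlas of peak sets.
4. **Which bound genes respond to losing the factor?** Per-gene Welch
   t-tests on log2 expression (fold change > 2, raw-p or BH-FDR
   significance modes), intersected with proximal (nearest-TSS) and distal
   (all TSSs within 100 kb) peak-gene links.
5. **Does the remodeler move promoter nucleosomes?** The +1 and −1
   nucleosomes flanking each TSS are called from smoothed acetylation
   coverage, and per-gene +1/−1 spacing is compared between conditions with
   a paired Wilcoxon signed-rank test whose small-sample mode is exact even
   under ties (full 2^n sign-assignment distribution by convolution over
   midranks).

A synthetic-data generator (`synthetic_config()`, `generate_bundle()`)
produces every input with recorded ground truth — planted chromatin
categories, planted nucleosome spacings, planted differential genes — so
each stage of the pipeline is verifiable end to end without any external
download. See `vignettes/chromstate-methods.Rmd` for the models,
assumptions and defaults.

## Worked example

```r
library(chromstate)

# synthetic study: 1000 peaks, study-like category mix, ground truth known
cfg <- synthetic_config(seed = 42)
gt  <- generate_genome(cfg)
pk  <- generate_peaks(cfg, gt)

cls <- classify_peaks(pk$peaks, gt$tss,
                      k4me3 = pk$marks$k4me3, k4me1 = pk$marks$k4me1,
                      k27ac = pk$marks$k27ac, k27me3 = pk$marks$k27me3)
class_composition(cls)
#> # A tibble: 9 × 5
#>   locality category              n frac_total frac_locality
#>   <chr>    <chr>             <int>      <dbl>         <dbl>
#> 1 proximal proximal_active      10       0.01           0.5
#> 2 proximal proximal_bivalent    10       0.01           0.5
#> 3 proximal proximal_other        0       0              0
#> # i 6 more rows
```

Each row is one chromatin-state category: `n` peaks, as a fraction of all
peaks (`frac_total`) and of the proximal or distal subset
(`frac_locality`). On this synthetic set the classifier recovers the
planted composition exactly (13/1/61/18/5% across the distal classes).

```r
# planted +1/-1 nucleosome spacing: wild type median 589 bp, mutant 482 bp
cfg_nuc <- synthetic_config(seed = 42, n_chrom = 1, n_genes = 500,
                            n_peaks = 10)
gt_nuc  <- generate_genome(cfg_nuc)
cov     <- generate_coverage(cfg_nuc, gt_nuc)
wt  <- call_flanking_nucleosomes(cov$tracks$wt,  gt_nuc$tss)
mut <- call_flanking_nucleosomes(cov$tracks$mut, gt_nuc$tss)
compare_spacing(wt, mut, "wt", "mut")
#> +1/-1 nucleosome spacing: wt vs mut over 500 paired genes
#>   median wt = 590 bp, median mut = 480 bp
#>   paired Wilcoxon (normal approximation): W = 5607.5, p = 8.813e-68
```

The caller recovers the planted medians to within one 10 bp bin, and the
paired test detects the ~107 bp narrowing decisively. The same kernel is
exact at small n:

```r
wilcoxon_signed_rank(c(12, 31, 27, 6, 50))
#> Paired Wilcoxon signed-rank test (exact)
#>   n = 5 pairs (0 zero differences)
#>   W = 0 (W+ = 15, W- = 0), two-sided p = 0.0625
```

`run_pipeline(pipeline_config(...))` (or a YAML config via
`read_pipeline_config()`) chains classification, cross-tissue matrices,
differential expression, peak-gene linkage and spacing comparison, writing
TSV/BED outputs plus a `summary.json`. `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` functions cover the result objects.

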