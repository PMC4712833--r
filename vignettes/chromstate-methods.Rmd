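---
title: "Methods: chromatin-state classification, peak-gene integration and nucleosome spacing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state classification, peak-gene integration and nucleosome spacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromstate)
```

chromstate implements the integrative analysis typically run around a
chromatin remodeler's ChIP-seq peak set in developing tissue: where does the
factor bind relative to promoters, in what chromatin state, how conserved is
binding across tissues, which bound genes change expression when the factor
is lost, and does the remodeler's loss move the +1/−1 nucleosomes that flank
transcription start sites. This vignette documents the models and procedures
behind each stage, the defaults and why they were chosen, and what the
synthetic-data generator does and does not emulate.

## Coordinate conventions and the interval engine

All intervals are 0-based half-open (BED convention) in a tibble with
columns `chrom`, `start`, `end`, `name`, `score`, `strand`,
`summit_offset`. GTF-style input (1-based closed) is converted at parse
time; for a minus-strand transcript the TSS is the record's end coordinate
minus one. Keeping one internal convention everywhere avoids off-by-one
drift between stages.

Overlap queries run on GenomicRanges index structures built from these
tibbles; the test suite checks them against quadratic brute-force scans, so
the index is an implementation detail rather than a trusted black box. Peak
strand is ignored in all overlap logic — histone marks and factor binding
are unstranded signals.

Every distance is measured from a peak *anchor*: the summit when a
narrowPeak summit offset is available, else the interval midpoint. The
summit is the most specific point the input provides; the midpoint is the
only option for plain BED. Nearest-TSS ties are broken by smaller absolute
distance, then lexicographically smallest gene id, so results are
deterministic under input reordering.

## Promoter-proximal vs distal, and the seven categories

A peak is **promoter-proximal** when the absolute signed distance from its
anchor to the nearest TSS is at most 1 kb (`proximal_bp`, inclusive at the
boundary), and distal otherwise. The 1 kb window is applied to the TSS; an
option to measure against gene bodies instead exists in the interval layer
(`distance_to_nearest_tss()` accepts any reference point set), but the TSS
reading is the default because promoter-state logic is TSS-centric.

Proximal peaks take one of three labels from histone-mark co-occurrence:

* **active** — overlaps both an H3K4me3 and an H3K27Ac peak;
* **bivalent** — overlaps both an H3K4me3 and an H3K27me3 peak;
* **other** — neither rule fires.

The two rules are not mutually exclusive: a promoter carrying H3K4me3 with
both H3K27Ac and H3K27me3 satisfies both. Such peaks carry the label
`bivalent` (the repressive mark is the more specific observation) but
`class_composition(mode = "rule")` tallies them under both rates, which is
why rule-mode percentages may sum past 100%. The default label-mode
composition is exclusive and sums to the peak total.

Distal peaks fall through a priority cascade over H3K4me1, H3K27Ac and
H3K27me3 overlap:

1. **bivalent** — all three marks;
2. **active** — H3K27Ac and H3K4me1;
3. **repressed** — H3K27me3 (in any remaining combination);
4. **latent** — H3K4me1 alone;
5. **isolated** — none of the three.

Written as plain co-occurrence rules these five classes are not a partition
— an H3K27Ac-only peak fits none of them, and an H3K27me3+H3K4me1 peak fits
two. The cascade resolves the double matches by priority (more marks, and
repressive over priming); the leftover H3K27Ac-only combination is reported
as a separate `other` bucket rather than silently dropped. A
`strict_five = TRUE` mode folds `other` into `latent` for workflows that
need exactly five distal counts summing to the distal total.

Mark overlap uses a 1 bp minimum (`min_overlap`), the weakest consistent
reading of "overlapping"; it is a parameter, not a constant, so stricter
reciprocal-style thresholds can be explored.

## Cross-tissue overlap and correlation

`overlap_matrix()` reports two complementary statistics per ordered pair of
peak sets. The **overlap fraction** of set A against set B is the fraction
of A's peaks sharing at least one base with any peak of B — asymmetric by
construction, and the natural reading of "X% of peaks overlap". The
**membership correlation** first merges all sets' peaks into a union atlas
of disjoint regions, encodes each set as a 0/1 membership vector over the
atlas, and takes Pearson correlations — symmetric and suitable for
heat-map clustering. A set whose membership vector is constant (it covers
every atlas region, or none) has no defined Pearson correlation; such pairs
are reported as 1 when the patterns are identical and 0 otherwise, and this
only arises in degenerate fixtures.

## Expression filtering, differential calls and signatures

Matrices are log2-scale RMA-style values, genes by samples. The expressed
filter keeps a gene when its mean within at least one sample group reaches
6 (`min_signal`) — a gene expressed in only one condition must survive.

The per-gene test is a **Welch two-sample t-test** on log2 values — the
standard un-moderated choice for small array groups, assuming nothing
about equal variances. Moderated alternatives (limma) would gain power at n = 3–4 but
change the null behavior; the un-moderated test keeps the calibration
property testable (null raw-p rate ≈ 5% at p < 0.05, verified over 20
simulation seeds). Benjamini–Hochberg q-values are computed across the
tested (post-filter) genes. Both significance modes are exposed because
published gene lists mix them: `sig_mode = "p"` (raw p < 0.05 with fold
change > 2, the headline-list rule) and `sig_mode = "fdr"` (BH q < 0.05).
A call is `up` when the log2 fold change (group 2 − group 1) reaches
log2(`fc_threshold`) and the significance rule fires; `down` symmetric.

Signature scoring z-scores each signature gene against the baseline group's
mean and SD, averages z across the signature's genes per sample, and
reports per-group means; the baseline group is zero-centered by
construction. This is the simplest score that yields baseline-centered
histograms; it is documented precisely so users can substitute a different
aggregation. Signature gene lists ship as editable TSVs — real lists are
study-specific inputs, not package data.

## Peak-gene linkage

Proximal peaks link to their nearest-TSS gene (the same assignment used for
the proximal/distal split). Distal peaks link to **every** gene whose TSS
lies within 100 kb (`distal_window`, inclusive at the boundary) of the peak
anchor — many-to-many, because the biological statement being reproduced
counts genes with a distal site nearby, not a unique target per peak. Gene
lists are deduplicated before counting, then intersected with the
DE directions to yield up/down target-gene lists.

## Nucleosome spacing from acetylation coverage

Coverage arrives as bedGraph and is rasterized to fixed 10 bp bins
(length-weighted mean per bin, gaps zero). Around each TSS the caller takes
a ±1 kb window (`search`), smooths with a 50 bp moving average
(`smooth_bandwidth`, edge-replicated), and finds local maxima. On the
strand-oriented axis, the **+1 nucleosome** is the highest local maximum
strictly downstream of the TSS and the **−1 nucleosome** the highest
strictly upstream; a side whose best maximum is below 10% of the window
maximum (`min_prominence`) yields no call, as do flat windows and windows
truncated by chromosome ends. Spacing is the +1 − −1 distance, always
positive. No published algorithm exists for calling flanking nucleosomes
from an acetylation track, so the package uses the simplest smoothed
local-maximum procedure with every knob exposed; window size, bandwidth and
prominence are declared defaults, not inferred values.

`compare_spacing()` restricts two call sets to the genes called in both
conditions, reports each condition's median over that intersection, and
tests the paired per-gene differences with the signed-rank test below. The
pairing unit is the gene — the only identity shared across conditions.
When several mutant replicates exist, each is compared against the
reference separately, one comparison per pair.

## The Wilcoxon signed-rank kernel

Zero differences are dropped (Wilcoxon's original treatment; Pratt's
zero-rank variant is available via `zero_method = "pratt"`). Absolute
differences are midranked under ties, `W = min(W+, W−)`. For n ≤ 25 pairs
the two-sided p-value is exact: the full null distribution of W+ over all
2^n sign assignments is built by convolution over the doubled midranks
(doubling makes tied midranks integral), and
p = 2·min(P(W+ ≤ w), P(W+ ≥ w)) capped at 1. Above n = 25 a normal
approximation with tie and continuity corrections takes over. This kernel
exists because `stats::wilcox.test()` abandons the exact distribution as
soon as ties or zeros appear, while paired spacing data in 10 bp bins is
tied almost surely. The test suite checks the convolution against literal
2^n enumeration (an independent code path) on 200 random instances and
against `wilcox.test` on tie-free data.

`bh_fdr()` delegates to `stats::p.adjust(method = "BH")` after validation;
the hand step-up lives only in the tests as its oracle. The nuclear shape
factor is the ratio of largest to smallest diameter with an elongation
threshold of 2 ("about twice as long as wide"); the package implements the
numeric rule only, not image segmentation.

## The synthetic-data generator

The generator is the package's ground-truth instrument: every pipeline
input can be produced with known answers, and the generator shares no
overlap, classification or peak-calling logic with the analysis code, so
agreement is evidence rather than circularity.

* **Genome and TSSs.** Genes sit on a jittered lattice (10 kb spacing,
  jitter < 2 kb, random strands), guaranteeing ≥ 5 kb between TSSs. Each
  chromosome ends in a gene-free zone where distal peaks are placed, ≥ 10 kb
  beyond the last TSS — a deliberate simplification that makes "distal"
  unambiguous by construction.
* **Peaks and marks.** Category counts follow largest-remainder rounding of
  the configured composition. The default mix mirrors the study-like
  landscape the pipeline targets: 13% distal active, 1% distal bivalent,
  61% isolated, 18% latent, 5% repressed, with the remaining 2% proximal
  split between active and bivalent. Proximal peaks are centered within
  500 bp of a distinct TSS; mark peaks are written strictly inside their
  factor peak's footprint in exactly the combination that makes the planted
  category the classifier's unique answer.
* **Coverage.** Per gene and condition, a spacing value is drawn from a
  truncated normal (defaults: median 589 bp wild type, 482 bp mutant, SD
  60 bp, truncated below 150 bp) and two Gaussian bumps (SD 75 bp, expected
  peak height 100) are centered ± spacing/2 around the TSS, with Poisson
  count noise and a flat background of 2 inside a ±1.5 kb window. Only the
  medians of the real spacing distribution are known, so a truncated normal
  is a declared modeling choice; the recovery target is the median, not the
  distribution shape.
* **Expression.** Baselines are Normal(7, 1.2) log2 units, so most genes
  clear the ≥ 6 filter; genes chosen to carry planted differential effects
  are redrawn until their baseline exceeds 6.2, making the planted truth
  recoverable after filtering. Effects (default ±1.5 log2 units) are
  planted on a fraction of the genes that received a proximal factor peak,
  tying the DE truth to the linkage chain. Signature blocks shift disjoint
  gene sets by a configured multiple of the noise SD in the mutant group.
* **Seeding.** One master seed expands into per-stage substreams
  (`seed * 101 +` a fixed stage offset), so any stage can be regenerated
  independently and all outputs are byte-identical across runs.

What the generator does **not** emulate: read-level sampling and fragment
size effects, peak-width and signal-strength distributions of real ChIP,
correlated mark domains spanning several peaks, genes closer than 5 kb,
probe-level microarray artifacts, and spacing distributions with realistic
skew. Passing the recovery tests therefore demonstrates that the
implementation computes its declared quantities correctly — not that those
defaults describe any particular real dataset.

## Numerical choices and degenerate inputs

* Boundary rules are inclusive: |distance| = 1000 is proximal, a TSS
  exactly 100 kb away is linked.
* Empty mark sets are legal (peaks classify as `other`/`isolated`); empty
  peak sets warn and return empty results; an empty overlap query set makes
  the overlap fraction `NA` (undefined) rather than 0.
* All-zero difference vectors give a degenerate Wilcoxon result (p = 1,
  W = 0) with a warning; fewer than 6 paired genes is an error because the
  exact test is uninformative there.
* Signal-matrix bins that extend past a chromosome edge are `NA`, never
  zero-filled, so profile averages are not biased downward at edges.
* Composition fractions must sum to 1 within 1e−9; BH inputs outside
  [0, 1] are errors, not clamped.

## Problem sizes used in the shipped checks

The package's own verification runs at deliberately small scale: peak sets
of 200–1000 intervals, 60–500 genes, 2000-gene expression matrices, 100
simulation seeds for the spacing comparison and 20 for DE calibration.
These sizes give tight Monte-Carlo bounds for the properties being checked
(median recovery within ±15 bp, detection in ≥ 95/100 seeds, null rate
within 5% ± 2%) while keeping the full suite fast; all of them scale up
linearly via `synthetic_config()` if heavier validation is wanted.

## Known limitations

* Chromatin-state assignment is rule-based co-occurrence, not a
  segmentation model (no ChromHMM-style multivariate states).
* Distal linkage is distance-only; no chromatin-contact information.
* The DE test is un-moderated; at n = 2–3 per group a moderated test would
  be more powerful.
* The nucleosome caller reads dyad positions from smoothed acetylation
  maxima, a proxy that inherits the mark's resolution; it is not an
  MNase-seq occupancy model.
* Overlap significance (permutation z-scores) is out of scope; overlap
  fractions and membership correlations are descriptive.
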