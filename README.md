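# histofold

Differential histone-modification regions from two-condition ChIP-seq, and
their integration with differential gene expression.

## What it does

Developmental transitions — the motivating case is porcine placental tissue
between gestational days 50 and 95, when placental folds form and expand —
reshape the chromatin marks H3K4me3 (active promoters) and H3K27ac (active
promoters and enhancers). histofold implements the analysis that detects
these changes from ChIP-seq and relates them to RNA-seq differential
expression:

1. **Differential regions.** Per mark, peak calls from both conditions are
   pooled and peaks within 1 kb are merged into one shared region set. Each
   region is quantified per condition as input-subtracted RPKM,

   RPKM = c·10⁹ / (L·N),  s = max(RPKM_IP − RPKM_INPUT, 0),

   (c = fragment count, L = region length, N = library size) and classified
   by the pseudocounted ratio FC = (s₂+1)/(s₁+1): *increased* if FC > 2,
   *decreased* if FC < 1/2, else *unchanged* — "more than 2-fold" is strict.
2. **Annotation.** Each region's midpoint is assigned to one of the feature
   categories (promoter ±3 kb with ≤1 kb / 1–2 kb / 2–3 kb bins, UTRs, exon,
   intron, ≤3 kb downstream of the TTS, distal intergenic), with
   promoter-first precedence; distributions are reported as percentages that
   sum to 100.
3. **TSS metaprofiles.** Strand-oriented ±5 kb profiles of IP RPKM in 100-bp
   bins, for genes split into high/low expression at a normalized value
   of 10.
4. **Integration.** DE genes (adjusted p < 0.01) are grouped by the marks
   gained (up genes) or lost (down genes) near their nearest-TSS-assigned
   regions into *neither / H3K4me3-only / H3K27ac-only / both*; up genes
   with a proximal (≤1 kb) H3K4me3 gain are tested for an expression shift
   with a paired two-sided Wilcoxon signed-rank test.
5. **Synthetic data.** `simulate_dataset()` generates every input above
   (GTF gene models, peak and fragment BEDs, counts/DE/expression tables)
   with known per-gene and per-region truth, so the whole chain is testable
   without external data.

All interval work sits on Bioconductor `GRanges`; BED/GTF/TSV readers and
writers convert at the boundary.

## Worked example

The `analysis/` directory holds the numbered drivers of the full workflow
(`01_simulate.R` … `05_report.R`), which write their tables under
`results/`. A condensed session:

```r
library(histofold)

sim <- simulate_dataset(sim_config(seed = 1), out_dir = "results/sim")
fr  <- sim$fragments$H3K4me3
regions <- call_differential_regions(
  sim$peaks$H3K4me3$c1, sim$peaks$H3K4me3$c2,
  fr$c1$ip, fr$c1$input, fr$c2$ip, fr$c2$input,
  mark = "H3K4me3", max_gap = 1000, fold_threshold = 2)
diff_region_counts(regions)
#>            mark increased decreased unchanged total
#> H3K4me3 H3K4me3       120        62       118   300
```

120 regions gained and 62 lost H3K4me3 signal between the conditions (the
truth behind this seed: 120 truly increased, 60 decreased, 120 stable —
`score_region_calls()` reports 100% sensitivity and 0% false-increase here).
Integration with the simulated DE table:

```r
de_split <- filter_de(sim$de, alpha = 0.01)
# regions_k27: same call_differential_regions() call on the H3K27ac inputs
flags <- assign_regions_to_genes(
  list(H3K4me3 = regions, H3K27ac = regions_k27), sim$gene_models)
group_genes(de_split, flags)$counts
#>      neither H3K4me3_only H3K27ac_only both
#> up         5           25            0   15
#> down      28            7            9    1
```

Of the 45 truly up-regulated genes, 40 (88.9%) fall in the K4-increased
groups — the built-in promoter coupling (70% of up genes) plus regions that
land near up genes by chance. The expression-shift test on the 33 up genes
with a proximal H3K4me3 gain gives V = 561, p = 2.3e-10, with mean
normalized expression rising from 8.94 to 10.80.

`run_pipeline(sim_config(seed = 1), "out/")` performs all stages in one call
and writes the report tables plus a `manifest.json` with checksums; a given
seed is byte-for-byte reproducible.

## Layout

* `R/` — package code: IO (`read_bed`, `read_gene_models`,
  `write_regions_tsv`), interval core (`merge_with_gap`,
  `count_overlapping`, `nearest_tss`), differential regions (`rpkm`,
  `region_signal`, `classify_change`, `call_differential_regions`),
  annotation (`annotate_regions`, `category_distribution`, `tss_profile`),
  integration (`filter_de`, `assign_regions_to_genes`, `group_genes`,
  `expression_shift_test`, `normalize_expression_standin`), simulation
  (`sim_config`, `simulate_dataset`, `score_region_calls`), and the
  orchestrator (`run_pipeline`).
* `analysis/` — numbered workflow drivers.
* `vignettes/histofold-methods.Rmd` — the methods vignette: model,
  parameters, generator design, numerical choices, limitations.
* `tests/testthat/` — unit, property and end-to-end tests, including
  brute-force oracle comparisons for the interval primitives.
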