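---
title: "Differential histone-modification regions and their integration with expression"
author: "histofold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential histone-modification regions and their integration with expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histofold)
```

## The analysis

histofold implements the analysis chain used to compare active-chromatin
histone marks between two biological conditions and to relate the changes to
gene expression. The motivating setting is a developmental comparison —
porcine placental tissue at two gestational stages (day 50, when placental
folds are being established, versus day 95, when they expand) — profiled with
ChIP-seq for H3K4me3 (a promoter mark of actively transcribed genes) and
H3K27ac (a mark of active promoters and enhancers), alongside RNA-seq. The
pipeline consumes peak calls and fragment alignments; peak calling and DE
model fitting themselves are upstream and out of scope.

### Differential modification regions

For one mark, peak calls from both conditions are pooled and any two peaks on
the same chromosome separated by at most `max_gap` = 1000 bp are merged
(transitively, boundary inclusive — BedTools `merge -d 1000` semantics). This
produces a single region set shared by both conditions, which is what makes a
between-condition comparison well defined: each merged region is then
quantified identically in each condition.

Quantification per region and condition:

* count the IP and the INPUT fragments overlapping the region by at least
  1 bp (strand-blind; no midpoint or fraction rule);
* normalize each count to RPKM,
  $\mathrm{RPKM} = \dfrac{c \cdot 10^9}{L \cdot N}$,
  with $c$ the count, $L$ the region length in bp and $N$ the library's total
  mapped fragments;
* the region signal is $s = \max(\mathrm{RPKM_{IP}} -
  \mathrm{RPKM_{INPUT}},\, 0)$.

The change classification uses the pseudocounted ratio
$\mathrm{FC} = (s_2 + p)/(s_1 + p)$ with $p = 1$: a region is *increased*
when $\mathrm{FC} > 2$, *decreased* when $\mathrm{FC} < 1/2$, otherwise
*unchanged*. "More than 2-fold" is strict, so a region at exactly 2-fold is
unchanged. Replicate libraries are pooled before counting (fragments
concatenated, library sizes summed), mirroring replicate pooling before peak
calling.

Three numerical choices deserve justification:

* **Flooring at zero.** An IP signal below its matched input is background,
  not negative enrichment; keeping negative values would make fold changes
  between two "absent" states look meaningful.
* **Pseudocount 1 on the signal scale.** Matches a log2(RPKM + 1) axis
  transform, keeps the ratio defined when a region is silent in one
  condition, and damps fold changes of very weak regions; it is configurable
  (`pseudocount`).
* **Strict inequalities.** The boundary case belongs to *unchanged* so that
  "increased" and "decreased" are exact mirror images; the label-swap
  antisymmetry (swap the conditions, increased and decreased swap exactly,
  with reciprocal fold changes) is a tested invariant.

A consequence of pooling and flooring, tested and documented: doubling every
library size with counts fixed halves all RPKMs; classes are invariant when
the pseudocount is rescaled proportionally, and with the pseudocount fixed
any class change is toward *unchanged* (the pseudocount weighs relatively
more as signals shrink).

### Genomic annotation

Each region is assigned by its **midpoint** to exactly one of the feature
categories, with precedence Promoter > 5' UTR > 3' UTR > Exon > Intron >
Downstream > Distal Intergenic. The promoter is ±3 kb of a TSS (strand-aware
which end is the TSS), binned by |distance| into ≤1 kb / 1–2 kb / 2–3 kb;
Downstream is ≤3 kb past the TTS in transcription orientation; a midpoint
hitting nothing is Distal Intergenic. The midpoint rule (rather than
any-overlap) makes the categories a partition — every region counted exactly
once, percentages summing to 100 — which is what a distribution plot
implicitly assumes. The promoter window is keyed to the *nearest* TSS, so a
region inside one gene's intron but within 3 kb of another gene's TSS is that
gene's promoter; this mirrors the promoter-first precedence of standard
ChIP-seq annotators. Reported six-way distributions collapse the two UTR
classes into "UTR"; the three promoter bins are additionally broken out
because the proximal (≤1 kb) bin carries the biological signal of interest.

Nearest-TSS assignment measures from the region midpoint to each TSS on the
same chromosome, signed positive downstream of the TSS in the gene's
orientation; |distance| ties break to the lexicographically smallest
`gene_id` (determinism), and no cross-chromosome assignment is ever made.

### TSS metaprofiles

`tss_profile()` bins a window of ±5 kb around every profiled TSS into 100-bp
bins, strand-oriented so upstream is always on the left, counts IP fragments
per bin (≥1 bp overlap) and converts to RPKM with the bin length and the
library size. Genes are split at a normalized expression value of 10 into
high (> 10) and low (≤ 10) strata and the profile is the stratum mean per
bin. Window and bin are configurable; the defaults resolve a ±1 kb promoter
peak with 20 bins across it. Windows are clipped at chromosome boundaries; a
stratum with no genes is omitted with a warning rather than fabricating an
empty row.

### Expression integration

The DE table (gene, log2 fold change, adjusted p) is split at adjusted
p < 0.01: *up* requires a positive log2FC, *down* negative; missing adjusted
p and exactly-zero fold changes are non-significant. Each differential
region is assigned to its single nearest-TSS gene, and per gene the pipeline
records whether any increased / decreased region of each mark is assigned,
plus proximal variants restricted to |distance| ≤ 1 kb. Up-regulated genes
are then grouped by their *increased* flags and down-regulated genes by
their *decreased* flags into four groups — neither, H3K4me3 only, H3K27ac
only, both — which partition each direction's genes; the 2 × 4 count table
and one-decimal (half-up) row percentages are the primary report. Both the
any-distance and the proximal flags are kept so that a proximal-only focus
set can be compared against the group table.

The association between proximal H3K4me3 gain and expression is tested on
the focus set (up-regulated genes with a proximal H3K4me3-increased region):
per gene, mean normalized expression per condition; across genes, a paired
two-sided Wilcoxon signed-rank test on the condition-2-minus-condition-1
differences. The test is distribution-free, appropriate for log-scale
expression summaries, and exact at the set sizes involved; a paired t-test
is available (`test = "t"`). If all paired differences are zero the test is
degenerate and p = 1 is returned by convention, with a warning.

Because upstream DE normalization is out of scope, the package ships a
documented stand-in transform, `normalize_expression_standin()`:
median-of-ratios size factors (the median over all-positive-count genes of
count / geometric mean) followed by log2(count / size factor + 1). It is the
same size-factor estimator used by standard RNA-seq tooling — the test suite
cross-checks it against an independent reference implementation — but the
log transform is not a variance-regularized transform: values for
low-count genes are noisier than a true regularized log, which matters only
for the high/low expression split, not for DE calls (which arrive
pre-computed).

## The synthetic-data generator

`simulate_dataset()` produces every input the pipeline consumes, with ground
truth, so each stage is testable end to end without external data. The
defaults define the study conditions and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| `n_chroms` × `chrom_length` | 3 × 2 Mb | smallest genome that exercises multi-chromosome logic with realistic gene spacing |
| `n_genes` | 300 | enough genes for stable group tables at desk scale |
| `gene_length_min/max` | 2–8 kb | compact but realistic gene bodies (3 exons, 200-bp UTRs) |
| `frac_de_up`, `frac_de_down` | 0.15 each | a substantial DE fraction, as in a strong developmental contrast |
| `n_enriched_per_mark` | 300 | one enriched region per ~20 kb |
| `region_width` | 1000 bp | typical promoter-proximal peak footprint |
| `frac_regions_increased/decreased` | 0.40 / 0.20 | an increase-skewed contrast, as observed for H3K4me3 in the motivating study |
| `fold_changed_min/max` | 4–8 | true changes comfortably above the 2-fold calling threshold |
| `fold_flat` | 5 | enriched-but-stable regions, the hard negatives for the caller |
| `background_rate` | 0.02 fragments/bp | ≥ 50 expected IP fragments in a changed region (0.02 × 1000 × 4 = 80) |
| `fragment_length` | 200 bp | sonicated-chromatin fragment size |
| `coupling_prob` | 0.7 | fraction of truly up genes hosting a promoter H3K4me3 gain, matching the ~68% reported in the motivating study |
| `n_samples_c1/c2` | 6 / 4 | the RNA-seq design of the motivating study |
| `nb_dispersion` | 0.05 | typical bulk RNA-seq overdispersion |

IP fragment counts in an enriched region follow
Poisson(background × length × fold) — implemented as uniform background over
the genome plus Poisson extra fragments at (fold − 1) × background inside
the region — and INPUT is background only. Peaks are emitted over regions
enriched (fold > 1) in that condition, with up to ±200 bp boundary jitter.
Truly up genes receive, with probability `coupling_prob`, an
H3K4me3-increased region whose midpoint lies within 1 kb of their TSS.
Adjusted p values are *simulated* (below the threshold for true DE genes,
above otherwise), not fitted: the package tests integration logic, not DE
inference. All randomness derives from one seed; identical configs produce
byte-identical files, which the determinism tests assert by checksum.

What the generator deliberately does **not** emulate — and hence what
passing tests do not show about real data: read-level sequences, mappability
and GC bias, copy-number distortions of INPUT, overdispersed (non-Poisson)
ChIP counts, replicate-to-replicate variance (replicates are pooled by
design), enhancer-like broad H3K27ac domains, and any genome-wide coupling
between expression *level* and promoter signal (only the up-gene/H3K4me3
gain coupling is built in; TSS-profile shape on real data is therefore
checked with constructed fixtures, not the simulator).

## Interval conventions and degenerate inputs

Internally all intervals are Bioconductor `GRanges` (1-based, closed), the
native convention of the R genomics stack; BED input (0-based half-open) is
converted at the boundary, GTF input passes through unchanged, and written
BED/region tables convert back to 0-based starts. Empty intervals
(start ≥ end in BED) are rejected with the offending line number, not
clipped. Chromosome names are compared exactly ("chr1" ≠ "1"); an explicit
alias map can be supplied at read time. Merging with `max_gap` g means gap
≤ g merges (boundary inclusive); merged output is sorted by natural
chromosome order, then start. Fragment counting requires disjoint regions
(as merging guarantees) and errors otherwise rather than silently
double-counting. A gene referenced only by its features gets a body
synthesized from the feature span, with a warning; unstranded gene records
are an error because TSS/TTS would be undefined.

## Problem sizes and runtime

The test suite and the acceptance script run at desk scale by design: the
oracle-equivalence checks use 200 random instances of ≤ 50 intervals ×
≤ 300 fragments against O(n²) brute force; the recovery benchmark simulates
500 enriched regions per mark on a 12-Mb genome (~1.3 M fragments across
8 libraries) and scores sensitivity/false-increase against truth; the
end-to-end determinism check runs the full pipeline twice on a 1.2-Mb,
60-gene configuration. These sizes keep every property measurable in
seconds-to-minutes while preserving the statistical regime the thresholds
refer to (expected IP fragments per changed region ≥ 50).

## Known limitations

* The fold-change rule has no significance assessment; a region with tiny
  signals in both conditions can be classified by noise. The pseudocount
  damps but does not remove this; the motivating analysis used the same
  rule.
* Single nearest-TSS assignment ignores genes whose promoters share a
  region with a closer TSS, and long-range (enhancer) regulation entirely.
* The stand-in expression transform is not variance-stabilized (above).
* Annotation is gene-level, not transcript-level; alternative TSSs are
  invisible.
* INPUT libraries are assumed mark-independent only insofar as the caller
  is handed explicit INPUT per call; sharing one INPUT across marks is the
  caller's choice.
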