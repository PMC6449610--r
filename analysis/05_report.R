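#!/usr/bin/env Rscript
# Stage 5: bookkeeping summary.
#
# Checks the synthetic run's tables for internal consistency (class counts
# partition each mark's region set; group counts partition each DE
# direction) and reproduces, from the published reference counts shipped
# with the package, the arithmetic identities of the original study's
# reported totals and percentages.

library(histofold)

rc <- do.call(rbind, lapply(c("H3K4me3", "H3K27ac"), function(mk)
  diff_region_counts(read_regions_tsv(sprintf("results/regions_%s.tsv", mk)))))
stopifnot(rc$increased + rc$decreased + rc$unchanged == rc$total)
gc <- read.delim("results/group_counts.tsv", check.names = FALSE)
stopifnot(rowSums(gc[2:5]) == gc$total)
cat("synthetic run: region classes and gene groups partition correctly\n\n")

ref <- reference_counts()
bk <- bookkeeping_summary(ref$region_counts, ref$gene_group_counts)
lines <- c(
  sprintf("reference DE genes: %d up + %d down = %d",
          bk$up_total, bk$down_total, bk$de_total),
  sprintf("reference differential regions: H3K4me3 %d, H3K27ac %d, total %d",
          bk$region_totals[["H3K4me3"]], bk$region_totals[["H3K27ac"]],
          bk$region_grand_total),
  sprintf("down genes with neither mark decreased: %d (%.1f%%)",
          bk$neither_down, bk$pct_down_neither),
  sprintf("up genes with H3K4me3-increased regions: %.1f%%", bk$pct_up_k4))
writeLines(lines, "results/reference_bookkeeping.txt")
cat(lines, sep = "\n")
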