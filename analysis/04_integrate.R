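#!/usr/bin/env Rscript
# Stage 4: integrate differential regions with differential expression.
#
# Filters the DE table at adjusted p < 0.01, assigns each differential
# region to its nearest-TSS gene, groups up genes by increased marks and
# down genes by decreased marks into the four-group classification, and
# tests whether up-regulated genes with a proximal (<= 1 kb) H3K4me3 gain
# shift their normalized expression between conditions (paired Wilcoxon
# signed-rank).

library(histofold)

gm <- read_gene_models("results/sim/genes.gtf")
de <- read.delim("results/sim/de.tsv")
expr_tab <- read.delim("results/sim/expr.tsv", check.names = FALSE)
expr <- as.matrix(expr_tab[-1])
rownames(expr) <- expr_tab$gene_id

regions <- list(
  H3K4me3 = read_regions_tsv("results/regions_H3K4me3.tsv"),
  H3K27ac = read_regions_tsv("results/regions_H3K27ac.tsv"))

de_split <- filter_de(de, alpha = 0.01)
flags <- assign_regions_to_genes(regions, gm, proximal_dist = 1000)
grp <- group_genes(de_split, flags)

counts_df <- data.frame(direction = rownames(grp$counts), grp$counts,
                        total = rowSums(grp$counts), check.names = FALSE)
write.table(counts_df, "results/group_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(grp$assignments, "results/gene_groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
pct <- group_percentages(grp$counts)
cat("gene groups (counts):\n"); print(counts_df, row.names = FALSE)
cat(sprintf("up genes in K4-increased groups: %.1f%% (K4_only + both)\n",
            pct["up", "H3K4me3_only"] + pct["up", "both"]))

focus <- de_split$up[de_split$up %in%
                       flags$gene_id[flags$H3K4me3_increased_proximal]]
cond <- ifelse(grepl("^c1_", colnames(expr)), "c1", "c2")
if (length(focus) >= 2) {
  sh <- expression_shift_test(focus, expr, cond)
  out <- c(sprintf("genes tested: %d (up-regulated, proximal H3K4me3 gain)", sh$n),
           sprintf("paired %s signed-rank: V = %g, p = %.3g", sh$method,
                   sh$statistic, sh$p_value),
           sprintf("mean normalized expression: %.3f (c1) -> %.3f (c2)",
                   sh$mean_c1, sh$mean_c2))
  writeLines(out, "results/association.txt")
  cat(out, sep = "\n")
} else {
  cat("fewer than 2 focus genes; association test skipped\n")
}
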