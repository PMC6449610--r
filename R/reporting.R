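# Reporting arithmetic: group-count bookkeeping and the published
# reference counts shipped with the package.

#' Published reference counts
#'
#' Loads the differential-region class counts and DE-gene group counts
#' reported by the porcine placenta study of gestational days 50 and 95
#' that this pipeline re-implements (H3K4me3/H3K27ac ChIP-seq integrated
#' with RNA-seq). These printed totals are used as fixture input to the
#' reporting arithmetic; they are not recomputable from raw data here.
#'
#' @return A list with data frames `region_counts` (mark, increased,
#'   decreased) and `gene_group_counts` (direction, total, k4_only,
#'   k27_only, both; `NA` where the study did not print the value).
#' @export
reference_counts <- function() {
  path <- function(f) system.file("extdata", f, package = "histofold",
                                  mustWork = TRUE)
  list(region_counts = read.delim(path("reference_region_counts.tsv")),
       gene_group_counts = read.delim(path("reference_gene_group_counts.tsv")))
}

#' Derive the 'neither' group size from a direction's bookkeeping
#'
#' The four groups partition a direction's DE genes, so
#' `neither = total - mark1_only - mark2_only - both`.
#'
#' @param total DE genes in the direction.
#' @param mark1_only,mark2_only,both The other three group sizes.
#' @return Integer count of genes in the `neither` group.
#' @export
derive_neither <- function(total, mark1_only, mark2_only, both) {
  as.integer(total - mark1_only - mark2_only - both)
}

#' Row percentages of a 2 x 4 group-count table
#'
#' @param counts Matrix as returned in `group_genes()$counts`.
#' @param digits Decimal places (half-up rounding; default 1).
#' @return Matrix of percentages, same dimnames, each row summing to ~100.
#' @export
group_percentages <- function(counts, digits = 1) {
  totals <- rowSums(counts)
  pct <- 100 * counts / ifelse(totals == 0, NA, totals)
  round_half_up(pct, digits)
}

#' Bookkeeping summary of region and gene-group counts
#'
#' Pure reporting arithmetic over class counts: per-mark and overall
#' differential-region totals, the DE total across directions, the derived
#' `neither` group where the other three groups are known, and the headline
#' percentages (one decimal, half-up).
#'
#' @param region_counts Data frame with `mark`, `increased`, `decreased`.
#' @param gene_group_counts Data frame with `direction`, `total`,
#'   `k4_only`, `k27_only`, `both` (`NA` allowed).
#' @return A named list of scalar totals and percentages.
#' @export
bookkeeping_summary <- function(region_counts, gene_group_counts) {
  rc <- region_counts
  gg <- gene_group_counts
  mark_total <- setNames(rc$increased + rc$decreased, rc$mark)
  row_of <- function(d) gg[gg$direction == d, , drop = FALSE]
  up <- row_of("up"); down <- row_of("down")
  neither_down <- derive_neither(down$total, down$k4_only, down$k27_only,
                                 down$both)
  list(
    de_total = sum(gg$total),
    up_total = up$total,
    down_total = down$total,
    region_totals = mark_total,
    region_grand_total = sum(mark_total),
    neither_down = neither_down,
    pct_down_neither = round_half_up(100 * neither_down / down$total, 1),
    pct_up_k4 = round_half_up(100 * up$k4_only / up$total, 1))
}
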