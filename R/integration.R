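# Integration of differential regions with differential expression:
# DE filtering, region-to-gene flags, the four-group classification, and
# the paired expression-shift test.

#' Split a differential-expression table into up/down/ns
#'
#' Applies the adjusted-p threshold: `up` iff `padj < alpha` and
#' `log2fc > 0`, `down` iff `padj < alpha` and `log2fc < 0`, otherwise `ns`
#' (including missing `padj` and exactly zero fold change).
#'
#' @param de Data frame with columns `gene_id`, `log2fc`, `padj`.
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @return A list: `table` (the input with a `direction` column), `up` and
#'   `down` (character vectors of gene ids).
#' @export
filter_de <- function(de, alpha = 0.01) {
  req <- c("gene_id", "log2fc", "padj")
  if (!all(req %in% names(de))) {
    stopf("DE table must have columns %s", paste(req, collapse = ", "))
  }
  bad <- !is.na(de$padj) & (de$padj < 0 | de$padj > 1)
  if (any(bad)) stopf("padj outside [0, 1] for gene %s",
                      de$gene_id[which(bad)[1]])
  sig <- !is.na(de$padj) & de$padj < alpha
  direction <- ifelse(sig & de$log2fc > 0, "up",
                      ifelse(sig & de$log2fc < 0, "down", "ns"))
  de$direction <- direction
  list(table = de,
       up = de$gene_id[direction == "up"],
       down = de$gene_id[direction == "down"])
}

#' Flag genes by the differential regions assigned to them
#'
#' Assigns every classified (non-unchanged) region to the single gene with
#' the nearest TSS and records, per gene and mark, whether at least one
#' increased and/or decreased region is assigned, plus proximal variants
#' restricted to regions whose midpoint lies within `proximal_dist` bp of
#' the TSS.
#'
#' @param regions_by_mark Named list of region-signal data frames, one per
#'   mark (names are the mark labels).
#' @param gene_models A `gene_models` object.
#' @param proximal_dist Proximal-promoter distance in bp (default 1000).
#' @return A data frame with one row per gene in `gene_models` and logical
#'   columns `<mark>_increased`, `<mark>_decreased`,
#'   `<mark>_increased_proximal`, `<mark>_decreased_proximal` per mark.
#' @export
assign_regions_to_genes <- function(regions_by_mark, gene_models,
                                    proximal_dist = 1000) {
  if (is.null(names(regions_by_mark)) || any(names(regions_by_mark) == "")) {
    stopf("regions_by_mark must be a named list (names = mark labels)")
  }
  gid <- S4Vectors::mcols(gene_models$genes)$gene_id
  out <- data.frame(gene_id = gid, stringsAsFactors = FALSE)
  for (mk in names(regions_by_mark)) {
    df <- regions_by_mark[[mk]]
    changed <- df[df$change_class != "unchanged", , drop = FALSE]
    flags <- matrix(FALSE, nrow = length(gid), ncol = 4,
                    dimnames = list(NULL, c("inc", "dec", "inc_prox", "dec_prox")))
    if (nrow(changed)) {
      nt <- nearest_tss(as_region_granges(changed), gene_models)
      idx <- match(nt$gene_id, gid)
      prox <- !is.na(nt$distance) & abs(nt$distance) <= proximal_dist
      inc <- changed$change_class == "increased"
      assigned <- !is.na(idx)
      flags[unique(idx[assigned & inc]), "inc"] <- TRUE
      flags[unique(idx[assigned & !inc]), "dec"] <- TRUE
      flags[unique(idx[assigned & inc & prox]), "inc_prox"] <- TRUE
      flags[unique(idx[assigned & !inc & prox]), "dec_prox"] <- TRUE
    }
    out[[paste0(mk, "_increased")]] <- flags[, "inc"]
    out[[paste0(mk, "_decreased")]] <- flags[, "dec"]
    out[[paste0(mk, "_increased_proximal")]] <- flags[, "inc_prox"]
    out[[paste0(mk, "_decreased_proximal")]] <- flags[, "dec_prox"]
  }
  out
}

#' Four-group classification of DE genes by histone-mark changes
#'
#' Up-regulated genes are grouped by which marks have an *increased* region
#' assigned to them, down-regulated genes by which marks have a *decreased*
#' region: `neither`, first mark only, second mark only, or `both`. The four
#' groups partition each direction's gene set.
#'
#' @param de_split Output of [filter_de()].
#' @param flags Output of [assign_regions_to_genes()].
#' @param marks Character vector of the two mark labels, in column-naming
#'   order (default `c("H3K4me3", "H3K27ac")`).
#' @param proximal If `TRUE`, use the proximal (<= 1 kb) flags instead of
#'   the any-distance flags.
#' @return A list: `assignments` (data frame `gene_id`, `direction`,
#'   `group`) and `counts` (2 x 4 integer matrix, rows `up`/`down`, columns
#'   `neither`, `<mark1>_only`, `<mark2>_only`, `both`).
#' @export
group_genes <- function(de_split, flags, marks = c("H3K4me3", "H3K27ac"),
                        proximal = FALSE) {
  if (length(marks) != 2) stopf("exactly two marks are required")
  if (length(intersect(de_split$up, de_split$down))) {
    stopf("gene(s) in both up and down sets")
  }
  suffix <- if (proximal) "_proximal" else ""
  col <- function(mk, what) paste0(mk, "_", what, suffix)
  need <- c(col(marks[1], "increased"), col(marks[2], "increased"),
            col(marks[1], "decreased"), col(marks[2], "decreased"))
  if (!all(need %in% names(flags))) {
    stopf("flags lack column(s): %s",
          paste(setdiff(need, names(flags)), collapse = ", "))
  }
  group_names <- c("neither", paste0(marks[1], "_only"),
                   paste0(marks[2], "_only"), "both")

  classify_dir <- function(genes, what) {
    i <- match(genes, flags$gene_id)
    f1 <- ifelse(is.na(i), FALSE, flags[[col(marks[1], what)]][i])
    f2 <- ifelse(is.na(i), FALSE, flags[[col(marks[2], what)]][i])
    ifelse(f1 & f2, group_names[4],
           ifelse(f1, group_names[2],
                  ifelse(f2, group_names[3], group_names[1])))
  }
  up_grp <- classify_dir(de_split$up, "increased")
  down_grp <- classify_dir(de_split$down, "decreased")

  assignments <- data.frame(
    gene_id = c(de_split$up, de_split$down),
    direction = rep(c("up", "down"), c(length(de_split$up), length(de_split$down))),
    group = c(up_grp, down_grp),
    stringsAsFactors = FALSE)
  counts <- rbind(
    up = table(factor(up_grp, levels = group_names)),
    down = table(factor(down_grp, levels = group_names)))
  list(assignments = assignments,
       counts = matrix(as.integer(counts), nrow = 2,
                       dimnames = list(c("up", "down"), group_names)))
}

#' Paired expression-shift test across conditions
#'
#' For a gene set (e.g. up-regulated genes with a proximal H3K4me3-increased
#' region), computes each gene's mean normalized expression per condition
#' and tests the paired per-gene differences (condition 2 minus condition 1)
#' with a two-sided Wilcoxon signed-rank test (or paired t-test).
#'
#' @param gene_ids Genes to test (>= 2).
#' @param expr Numeric matrix of normalized expression, genes x samples,
#'   with gene ids as rownames.
#' @param condition Character/factor of length `ncol(expr)` with exactly two
#'   levels; the first level encountered is condition 1 unless `expr` has a
#'   factor with explicit levels.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return A list: `method`, `n`, `statistic`, `p_value`, `mean_c1`,
#'   `mean_c2` (means over genes of the per-gene condition means), and
#'   `median_shift` (median paired difference).
#' @export
expression_shift_test <- function(gene_ids, expr, condition,
                                  test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (length(gene_ids) < 2) stopf("need at least 2 genes")
  if (length(condition) != ncol(expr)) {
    stopf("condition must have one entry per expression column")
  }
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stopf("exactly two conditions are required")
  missing_g <- setdiff(gene_ids, rownames(expr))
  if (length(missing_g)) {
    stopf("gene(s) absent from expression matrix: %s",
          paste(utils::head(missing_g, 5), collapse = ", "))
  }
  lev <- levels(condition)
  m1 <- rowMeans(expr[gene_ids, condition == lev[1], drop = FALSE])
  m2 <- rowMeans(expr[gene_ids, condition == lev[2], drop = FALSE])
  d <- m2 - m1
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1 by convention")
    return(list(method = test, n = length(d), statistic = NA_real_,
                p_value = 1, mean_c1 = mean(m1), mean_c2 = mean(m2),
                median_shift = 0))
  }
  ht <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(m2, m1, paired = TRUE,
                                        alternative = "two.sided"))
  } else {
    stats::t.test(m2, m1, paired = TRUE, alternative = "two.sided")
  }
  list(method = test, n = length(d),
       statistic = unname(ht$statistic), p_value = ht$p.value,
       mean_c1 = mean(m1), mean_c2 = mean(m2),
       median_shift = stats::median(d))
}

#' Median-of-ratios normalized log2 expression
#'
#' A documented stand-in for a regularized-log transform: per-sample size
#' factors are the median, over genes with all-positive counts, of the
#' count divided by the gene's geometric mean across samples; normalized
#' values are `log2(count / size_factor + 1)`.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @return A list: `values` (matrix of normalized log2 values, same
#'   dimensions) and `size_factors` (named numeric per sample).
#' @export
normalize_expression_standin <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("counts must be non-negative")
  usable <- rowSums(counts > 0) == ncol(counts)
  if (!any(usable)) {
    stopf("no gene with all-positive counts; cannot estimate size factors")
  }
  log_gm <- rowMeans(log(counts[usable, , drop = FALSE]))
  sf <- apply(counts[usable, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_gm))
  })
  values <- log2(sweep(counts, 2, sf, "/") + 1)
  list(values = values, size_factors = sf)
}
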