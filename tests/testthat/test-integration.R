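test_that("filter_de partitions genes by adjusted p and fold-change sign", {
  de <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(1.2, -0.5, 0, 2.0, -1.1),
    padj = c(0.001, 0.02, 1e-4, NA, 0.009),
    stringsAsFactors = FALSE)
  sp <- filter_de(de, alpha = 0.01)
  expect_equal(sp$up, "a")          # significant, positive
  expect_equal(sp$down, "e")        # significant, negative
  # b: padj above alpha; c: zero fold change; d: missing padj
  expect_equal(sp$table$direction, c("up", "ns", "ns", "ns", "down"))
  de$padj[1] <- 1.5
  expect_error(filter_de(de), "padj")
})

# fixture: two genes, one increased K4 region 400 bp upstream of g1's TSS,
# one decreased K27 region 5 kb from g2's TSS
flag_fixture <- function() {
  gm <- toy_gene_models(data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start0 = c(20000, 60000), end0 = c(28000, 66000),
    strand = "+", stringsAsFactors = FALSE))
  mk_regions <- function(s0, e0, cls) {
    data.frame(chrom = "chr1", start = s0, end = e0, mark = "x",
               change_class = cls, stringsAsFactors = FALSE)
  }
  list(gm = gm,
       k4 = mk_regions(19100, 20100, "increased"),   # midpoint 19600
       k27 = mk_regions(54500, 55500, "decreased"))  # midpoint 55000
}

test_that("assign_regions_to_genes sets per-gene and proximal flags", {
  fx <- flag_fixture()
  flags <- assign_regions_to_genes(list(H3K4me3 = fx$k4, H3K27ac = fx$k27),
                                   fx$gm)
  g1 <- flags[flags$gene_id == "g1", ]
  g2 <- flags[flags$gene_id == "g2", ]
  expect_true(g1$H3K4me3_increased && g1$H3K4me3_increased_proximal)
  expect_false(g1$H3K4me3_decreased || g1$H3K27ac_decreased)
  # K27 region is nearest to g2 (5 kb away): flagged, but not proximal
  expect_true(g2$H3K27ac_decreased)
  expect_false(g2$H3K27ac_decreased_proximal)
  expect_false(g2$H3K4me3_increased)

  # no differential regions -> all flags false
  none <- assign_regions_to_genes(
    list(H3K4me3 = fx$k4[0, ], H3K27ac = fx$k27[0, ]), fx$gm)
  expect_false(any(as.matrix(none[-1])))
})

test_that("a region equidistant between two TSSs goes to the smaller gene_id only", {
  gm <- toy_gene_models(data.frame(
    gene_id = c("gB", "gA"), chrom = "chr1",
    start0 = c(10000, 20000), end0 = c(14000, 24000),
    strand = "+", stringsAsFactors = FALSE))
  reg <- data.frame(chrom = "chr1", start = 14500, end = 15500, mark = "x",
                    change_class = "increased", stringsAsFactors = FALSE)
  flags <- assign_regions_to_genes(list(H3K4me3 = reg, H3K27ac = reg[0, ]), gm)
  expect_equal(flags$gene_id[flags$H3K4me3_increased], "gA")
})

test_that("group_genes produces the four-group partition and count table", {
  # 10 up genes: 6 K4-only, 1 both, 0 K27-only, 3 neither
  up <- sprintf("u%02d", 1:10)
  flags <- data.frame(
    gene_id = up,
    H3K4me3_increased = c(rep(TRUE, 7), rep(FALSE, 3)),
    H3K27ac_increased = c(rep(FALSE, 6), TRUE, rep(FALSE, 3)),
    H3K4me3_decreased = FALSE, H3K27ac_decreased = FALSE,
    stringsAsFactors = FALSE)
  de_split <- list(up = up, down = character(0))
  grp <- group_genes(de_split, flags)
  expect_equal(unname(grp$counts["up", ]), c(3L, 6L, 0L, 1L))
  expect_equal(sum(grp$counts["up", ]), length(up))
  expect_equal(nrow(grp$assignments), 10)
  expect_setequal(grp$assignments$group[grp$assignments$gene_id %in% up[1:6]],
                  "H3K4me3_only")

  # no DE genes -> all-zero table
  empty <- group_genes(list(up = character(0), down = character(0)), flags)
  expect_true(all(empty$counts == 0))
  expect_error(group_genes(list(up = "u01", down = "u01"), flags), "both")
})

test_that("expression_shift_test returns p = 1 for identical conditions", {
  expr <- matrix(rep(c(5, 7, 9), 4), nrow = 3,
                 dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  cond <- c("c1", "c1", "c2", "c2")
  expect_warning(res <- expression_shift_test(c("a", "b", "c"), expr, cond),
                 "zero")
  expect_equal(res$p_value, 1)
  expect_error(expression_shift_test("a", expr, cond), "at least 2")
})

test_that("a uniform positive shift across 20 genes gives the exact signed-rank p", {
  n <- 20
  set.seed(55)
  base <- matrix(rnorm(n * 4, mean = 10), nrow = n,
                 dimnames = list(sprintf("g%02d", 1:n), sprintf("c1_s%d", 1:4)))
  # distinct per-gene shifts (no ties) keep the exact null distribution
  shift <- 5 + (1:n) / 100
  expr <- cbind(base, base + shift)
  colnames(expr)[5:8] <- sprintf("c2_s%d", 1:4)
  cond <- c(rep("c1", 4), rep("c2", 4))
  res <- expression_shift_test(rownames(expr), expr, cond)
  # all n differences positive: two-sided exact p = 2 / 2^n
  expect_equal(res$p_value, 2 * stats::psignrank(0, n), tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$mean_c2 - res$mean_c1, mean(shift), tolerance = 1e-9)

  # antisymmetry: swapping conditions flips the shift, keeps p
  res_swap <- expression_shift_test(rownames(expr), expr,
                                    factor(cond, levels = c("c2", "c1")))
  expect_equal(res_swap$p_value, res$p_value)
  expect_equal(res_swap$median_shift, -res$median_shift)
})

test_that("median-of-ratios stand-in has unit factors for identical columns", {
  counts <- matrix(rep(c(10L, 100L, 1000L), 3), nrow = 3,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  nr <- normalize_expression_standin(counts)
  expect_equal(unname(nr$size_factors), rep(1, 3))
  expect_equal(nr$values, log2(counts + 1), ignore_attr = TRUE)
  expect_equal(nr$values["a", 1], log2(11))
})

test_that("a doubled sample gets size factor 2 and equal normalized values", {
  set.seed(66)
  counts <- matrix(rpois(300, 100), nrow = 100)
  counts <- cbind(counts, 2L * counts[, 1])
  dimnames(counts) <- list(sprintf("g%03d", 1:100), sprintf("s%d", 1:4))
  nr <- normalize_expression_standin(counts)
  expect_equal(unname(nr$size_factors[4] / nr$size_factors[1]), 2)
  expect_equal(nr$values[, 4], nr$values[, 1])
  expect_true(all(nr$values[counts == 0] == 0))
  expect_error(normalize_expression_standin(matrix(0L, 2, 2)), "size factors")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  counts <- matrix(rnbinom(600, mu = 200, size = 10), nrow = 150)
  dimnames(counts) <- list(sprintf("g%03d", 1:150), sprintf("s%d", 1:4))
  nr <- normalize_expression_standin(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(nr$size_factors), unname(ref), tolerance = 1e-8)
})

test_that("coupled up-regulated genes are enriched for K4 groups on synthetic data", {
  sim <- cached("coupling_sim", simulate_dataset(small_sim_config(seed = 5)))
  regions <- lapply(setNames(c("H3K4me3", "H3K27ac"),
                             c("H3K4me3", "H3K27ac")), function(mk) {
    fr <- sim$fragments[[mk]]
    call_differential_regions(sim$peaks[[mk]]$c1, sim$peaks[[mk]]$c2,
                              fr$c1$ip, fr$c1$input, fr$c2$ip, fr$c2$input,
                              mark = mk)
  })
  de_split <- filter_de(sim$de)
  flags <- assign_regions_to_genes(regions, sim$gene_models)
  grp <- group_genes(de_split, flags)
  truly_up <- sim$truth_genes$gene_id[sim$truth_genes$true_direction == "up"]
  k4_any <- flags$gene_id[flags$H3K4me3_increased]
  frac_up <- mean(truly_up %in% k4_any)
  non_de <- sim$truth_genes$gene_id[sim$truth_genes$true_direction == "ns"]
  frac_ns <- mean(non_de %in% k4_any)
  expect_gt(frac_up, frac_ns)
  # group counts per direction sum to the direction's DE count
  expect_equal(unname(rowSums(grp$counts)),
               c(length(de_split$up), length(de_split$down)))
})
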