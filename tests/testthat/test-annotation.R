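# A small two-gene landscape used across annotation tests:
# gPlus: chr1 0-based [20000, 30000), '+', TSS 20000
# gMinus: chr1 [50000, 58000), '-', TSS 57999
anno_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gPlus", "gMinus"), chrom = "chr1",
    start0 = c(20000, 50000), end0 = c(30000, 58000),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  feats <- data.frame(
    gene_id = c("gPlus", "gPlus", "gPlus", "gPlus",
                "gMinus", "gMinus"),
    chrom = "chr1",
    type = c("exon", "exon", "five_prime_utr", "three_prime_utr",
             "exon", "exon"),
    start0 = c(20000, 28000, 20000, 29800, 50000, 57000),
    end0 = c(21000, 30000, 20200, 30000, 51000, 58000),
    strand = c(rep("+", 4), rep("-", 2)), stringsAsFactors = FALSE)
  toy_gene_models(genes, feats)
}

test_that("annotate_regions applies the precedence rules on the midpoint", {
  gm <- anno_gene_models()
  cases <- list(
    # midpoint 500 bp upstream of gPlus TSS -> Promoter <=1kb
    list(r = c(19400, 19600), cat = "Promoter (<=1kb)", gene = "gPlus",
         dist = -500L),
    # midpoint 1.5 kb upstream -> Promoter 1-2kb bin
    list(r = c(18400, 18600), cat = "Promoter (1-2kb)", gene = "gPlus",
         dist = -1500L),
    # midpoint 2.5 kb downstream of TSS, inside the gene -> still Promoter
    list(r = c(22400, 22600), cat = "Promoter (2-3kb)", gene = "gPlus",
         dist = 2500L),
    # mid-gene in an intron (between exons, > 3 kb from any TSS)
    list(r = c(24900, 25100), cat = "Intron", gene = "gPlus", dist = 5000L),
    # inside the second exon of gPlus, > 3 kb from both TSSs
    list(r = c(28450, 28650), cat = "Exon", gene = "gPlus", dist = 8550L),
    # 3' UTR beats plain exon
    list(r = c(29850, 29950), cat = "3' UTR", gene = "gPlus", dist = 9900L),
    # downstream of gPlus TTS (TTS at 0-based 29999, '+')
    list(r = c(31900, 32100), cat = "Downstream (<=3kb)", gene = "gPlus",
         dist = 12000L),
    # downstream of gMinus: '-' strand TTS at 0-based 50000, downstream is
    # decreasing coordinates
    list(r = c(47900, 48100), cat = "Downstream (<=3kb)", gene = "gMinus",
         dist = 9999L),
    # far from everything -> Distal Intergenic
    list(r = c(89900, 90100), cat = "Distal Intergenic", gene = "gMinus",
         dist = -32001L))
  regions <- df_to_gr(data.frame(
    chrom = "chr1",
    start0 = vapply(cases, function(x) x$r[1], numeric(1)),
    end0 = vapply(cases, function(x) x$r[2], numeric(1))))
  ann <- annotate_regions(regions, gm)
  expect_equal(ann$category, vapply(cases, `[[`, character(1), "cat"))
  expect_equal(ann$gene_id, vapply(cases, `[[`, character(1), "gene"))
  expect_equal(ann$distance, vapply(cases, `[[`, integer(1), "dist"))
  expect_equal(ann$promoter_bin != "n/a",
               startsWith(ann$category, "Promoter"))
})

test_that("a promoter window of another gene wins over the host gene's intron", {
  # gHost's intron contains the midpoint, but gNear's TSS is 2.5 kb away
  genes <- data.frame(
    gene_id = c("gHost", "gNear"), chrom = "chr1",
    start0 = c(10000, 27500), end0 = c(26000, 29000),
    strand = "+", stringsAsFactors = FALSE)
  feats <- data.frame(gene_id = "gHost", chrom = "chr1", type = "exon",
                      start0 = 10000, end0 = 11000, strand = "+",
                      stringsAsFactors = FALSE)
  gm <- toy_gene_models(genes, feats)
  ann <- annotate_regions(gr0("chr1", 24900, 25100), gm)  # midpoint 25000
  expect_equal(ann$category, "Promoter (2-3kb)")
  expect_equal(ann$gene_id, "gNear")
  expect_equal(ann$distance, -2500L)
})

test_that("a midpoint on a geneless chromosome is Distal with no nearest gene", {
  gm <- anno_gene_models()
  ann <- annotate_regions(gr0("chrM", 100, 200), gm)
  expect_equal(ann$category, "Distal Intergenic")
  expect_true(is.na(ann$gene_id) && is.na(ann$distance))
})

test_that("every region gets exactly one category and the distribution sums to 100", {
  set.seed(44)
  gm <- anno_gene_models()
  regions <- df_to_gr(rand_intervals(150, n_chroms = 1, max_pos = 95000,
                                     max_len = 800))
  ann <- annotate_regions(regions, gm)
  expect_equal(nrow(ann), 150)
  expect_true(all(ann$category %in%
                    histofold:::annotation_categories()))
  dist <- category_distribution(ann)
  expect_equal(sum(dist$n), 150)
  expect_equal(sum(dist$percent), 100, tolerance = 0.01)
  expect_error(category_distribution(ann[0, ]), "no annotated")

  # 4-region arithmetic: 2 promoter(<=1kb), 1 intron, 1 distal -> 50/25/25
  four <- annotate_regions(gr0("chr1", c(19600, 20100, 24900, 89900),
                               c(19800, 20300, 25100, 90100)), gm)
  d4 <- category_distribution(four)
  expect_equal(d4$percent[d4$category == "Promoter (<=1kb)"], 50)
  expect_equal(d4$percent[d4$category == "Intron"], 25)
  expect_equal(d4$percent[d4$category == "Distal Intergenic"], 25)
})

test_that("annotation is invariant to gene input order", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start0 = c(5000, 40000, 70000), end0 = c(15000, 48000, 76000),
    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  set.seed(8)
  regions <- df_to_gr(rand_intervals(60, n_chroms = 1, max_pos = 80000))
  a <- annotate_regions(regions, toy_gene_models(genes))
  b <- annotate_regions(regions, toy_gene_models(genes[c(3, 1, 2), ]))
  expect_equal(a, b)
})

test_that("tss_profile is flat for uniform coverage and strand-oriented", {
  genes <- data.frame(
    gene_id = c("gp", "gn"), chrom = "chr1",
    start0 = c(30000, 60000), end0 = c(40000, 70000),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  gm <- toy_gene_models(genes)
  expr <- c(gp = 12, gn = 2)

  # fragments tiled uniformly: every 100-bp bin overlaps the same number
  fs <- uniform_fs(genome_len = 1e5, step = 50, frag_len = 100)
  pr <- tss_profile(fs, gm, expr, window = 2000, bin = 100)
  expect_equal(dim(pr$matrix), c(2, 40))
  expect_equal(rownames(pr$matrix), c("high", "low"))
  for (s in c("high", "low")) {
    v <- pr$matrix[s, ]
    expect_true(max(v) - min(v) < 1e-9 * max(v))
  }

  # fragments only upstream of the '-' gene's TSS (higher coordinates)
  # must appear in left-hand (upstream) bins of the low stratum
  up_fs <- make_fs("chr1", seq(70600, 71400, by = 50),
                   seq(70700, 71500, by = 50))
  pr2 <- suppressWarnings(tss_profile(up_fs, gm, expr, window = 2000,
                                      bin = 100))
  low <- pr2$matrix["low", ]
  expect_true(sum(low[pr2$bin_mid < 0]) > 0)
  expect_equal(sum(low[pr2$bin_mid > 0]), 0)
})

test_that("high-expression promoter fragments peak centrally in the high stratum", {
  genes <- data.frame(
    gene_id = sprintf("g%d", 1:4), chrom = "chr1",
    start0 = c(20000, 45000, 70000, 95000),
    end0 = c(28000, 53000, 78000, 103000),
    strand = "+", stringsAsFactors = FALSE)
  gm <- toy_gene_models(genes)
  expr <- c(g1 = 15, g2 = 14, g3 = 3, g4 = 2)
  # fragments concentrated within +/- 1 kb of the two high-expression TSSs
  s0 <- c(rep(seq(19100, 20900, by = 30), 2), rep(seq(44100, 45900, by = 30), 2))
  fs <- make_fs("chr1", s0, s0 + 100)
  pr <- tss_profile(fs, gm, expr, window = 5000, bin = 100)
  high <- pr$matrix["high", ]
  central <- abs(pr$bin_mid) <= 1000
  expect_true(mean(high[central]) > 10 * mean(high[!central] + 1e-12))
  expect_equal(unname(sum(pr$matrix["low", ])), 0)
})

test_that("doubling the window preserves shared central bins", {
  genes <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                      start0 = c(30000, 60000), end0 = c(38000, 68000),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  gm <- toy_gene_models(genes)
  expr <- c(a = 12, b = 5)
  set.seed(12)
  s0 <- sample.int(90000, 4000)
  fs <- make_fs("chr1", s0, s0 + 150)
  p1 <- tss_profile(fs, gm, expr, window = 2000, bin = 100)
  p2 <- tss_profile(fs, gm, expr, window = 4000, bin = 100)
  expect_equal(ncol(p2$matrix), 2 * ncol(p1$matrix))
  shared <- match(p1$bin_mid, p2$bin_mid)
  expect_equal(p2$matrix[, shared], p1$matrix,
               ignore_attr = TRUE)
})

test_that("an empty stratum is omitted with a warning", {
  genes <- data.frame(gene_id = "solo", chrom = "chr1", start0 = 30000,
                      end0 = 38000, strand = "+", stringsAsFactors = FALSE)
  gm <- toy_gene_models(genes)
  fs <- uniform_fs()
  expect_warning(pr <- tss_profile(fs, gm, c(solo = 20), window = 1000,
                                   bin = 100), "low")
  expect_equal(rownames(pr$matrix), "high")
  expect_error(tss_profile(fs, gm, c(other = 1)), "no expression value")
})
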