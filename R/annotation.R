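# Genomic feature annotation of regions and TSS metaprofiles.

annotation_categories <- function() {
  c("Promoter (<=1kb)", "Promoter (1-2kb)", "Promoter (2-3kb)",
    "5' UTR", "3' UTR", "Exon", "Intron", "Downstream (<=3kb)",
    "Distal Intergenic")
}

#' Annotate regions with genomic feature categories
#'
#' Assigns each region, by its midpoint, to exactly one feature category
#' with precedence Promoter > 5' UTR > 3' UTR > Exon > Intron > Downstream >
#' Distal Intergenic. The promoter is the strand-aware window of
#' `promoter_halfwidth` bp either side of a TSS (the nearest TSS decides,
#' so a region inside one gene's intron but within the promoter window of
#' another gene is Promoter); promoter hits are binned by |distance to TSS|
#' into <=1kb, 1-2kb and 2-3kb. Downstream is within `downstream_len` bp
#' past the TTS in transcription orientation. A midpoint hitting none of
#' these windows is Distal Intergenic; on a chromosome without genes, the
#' nearest gene and distance are `NA`.
#'
#' @param regions A `GRanges` or a region-signal data frame.
#' @param gene_models A `gene_models` object.
#' @param promoter_halfwidth Promoter half-width in bp (default 3000).
#' @param downstream_len Downstream window length in bp (default 3000).
#' @return A data frame, one row per region: `chrom`, `start`, `end`
#'   (0-based half-open), `category` (promoter bins broken out),
#'   `top_level` (six-way category with UTRs collapsed), `promoter_bin`,
#'   `gene_id`, `distance` (signed bp to the nearest TSS).
#' @export
annotate_regions <- function(regions, gene_models, promoter_halfwidth = 3000,
                             downstream_len = 3000) {
  extra <- if (is.data.frame(regions)) {
    regions[setdiff(names(regions), c("chrom", "start", "end"))]
  } else {
    NULL
  }
  gr <- as_region_granges(regions)
  nt <- nearest_tss(gr, gene_models)
  mid0 <- midpoint0(gr)
  mids <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                 IRanges::IRanges(mid0 + 1L, mid0 + 1L))

  # seqlevels of regions and annotation may legitimately differ (e.g. a
  # region on a chromosome without genes); the mismatch warning is noise
  count_hits <- function(q, s) {
    suppressWarnings(GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE))
  }
  hit <- function(feature_grl) {
    feats <- unlist(feature_grl, use.names = FALSE)
    if (length(feats) == 0) return(logical(length(gr)))
    count_hits(mids, feats) > 0
  }

  genes <- gene_models$genes
  gstr <- as.character(GenomicRanges::strand(genes))
  tts1 <- S4Vectors::mcols(genes)$tts
  down_start <- ifelse(gstr == "+", tts1 + 1L, pmax(tts1 - downstream_len, 1L))
  down_end <- ifelse(gstr == "+", tts1 + downstream_len, tts1 - 1L)
  ok <- down_end >= down_start
  downstream_windows <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes))[ok],
    IRanges::IRanges(down_start[ok], down_end[ok]))

  in_promoter <- !is.na(nt$distance) & abs(nt$distance) <= promoter_halfwidth
  in_utr5 <- hit(gene_models$utr5)
  in_utr3 <- hit(gene_models$utr3)
  in_exon <- hit(gene_models$exons)
  in_gene <- count_hits(mids, genes) > 0
  in_down <- if (length(downstream_windows)) {
    count_hits(mids, downstream_windows) > 0
  } else {
    logical(length(gr))
  }

  top <- rep("Distal Intergenic", length(gr))
  top[in_down] <- "Downstream (<=3kb)"
  top[in_gene] <- "Intron"
  top[in_exon] <- "Exon"
  top[in_utr3] <- "3' UTR"
  top[in_utr5] <- "5' UTR"
  top[in_promoter] <- "Promoter"

  absd <- abs(nt$distance)
  bin <- rep("n/a", length(gr))
  bin[in_promoter & absd <= promoter_halfwidth] <- "2-3kb"
  bin[in_promoter & absd <= 2000] <- "1-2kb"
  bin[in_promoter & absd <= 1000] <- "<=1kb"

  category <- ifelse(top == "Promoter", paste0("Promoter (", bin, ")"), top)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    category = category,
    top_level = ifelse(top %in% c("5' UTR", "3' UTR"), "UTR", top),
    promoter_bin = bin,
    gene_id = nt$gene_id,
    distance = nt$distance,
    stringsAsFactors = FALSE)
  if (!is.null(extra) && ncol(extra)) out <- cbind(out, extra)
  out
}

#' Percentage distribution of regions over feature categories
#'
#' @param annotated Output of [annotate_regions()] (at least one row).
#' @return A data frame with `category`, `n` and `percent` for all nine
#'   reported categories (three promoter bins broken out); percentages sum
#'   to 100.
#' @export
category_distribution <- function(annotated) {
  if (!nrow(annotated)) stopf("no annotated regions")
  lev <- annotation_categories()
  n <- table(factor(annotated$category, levels = lev))
  data.frame(category = lev,
             n = as.integer(n),
             percent = 100 * as.integer(n) / nrow(annotated),
             stringsAsFactors = FALSE)
}

#' TSS metaprofile stratified by expression level
#'
#' Builds the mean ChIP signal profile around gene TSSs, in strand-oriented
#' bins (upstream on the left), for genes split into high and low expression
#' strata at `expr_threshold` (high: value > threshold). Per gene and bin,
#' fragments overlapping the bin by >= 1 bp are counted and converted to
#' RPKM with the bin length and the library size; the profile is the mean
#' over the stratum's genes. Windows are clipped at chromosome start; genes
#' that close to an end contribute their remaining bins.
#'
#' @param fragments A `fragment_set` (typically an IP library).
#' @param gene_models A `gene_models` object.
#' @param expression Named numeric vector of normalized expression values
#'   (rld-like), one per profiled gene; every gene in `gene_models` must be
#'   present.
#' @param expr_threshold Expression split point (default 10).
#' @param window Half-width of the profiled window in bp (default 5000).
#' @param bin Bin size in bp (default 100; must divide `window`).
#' @return An object of class `tss_profile`: list with `window`, `bin`,
#'   `bin_mid` (relative bin centers), `n_genes` (per stratum) and `matrix`
#'   (rows `high`/`low`, mean RPKM per bin). A stratum with no genes is
#'   omitted with a warning.
#' @export
tss_profile <- function(fragments, gene_models, expression,
                        expr_threshold = 10, window = 5000, bin = 100) {
  if (!methods::is(fragments, "fragment_set")) {
    stopf("fragments must be a fragment_set")
  }
  if (window %% bin != 0) stopf("bin must divide window")
  genes <- gene_models$genes
  gid <- S4Vectors::mcols(genes)$gene_id
  missing_expr <- setdiff(gid, names(expression))
  if (length(missing_expr)) {
    stopf("no expression value for gene(s): %s",
          paste(utils::head(missing_expr, 5), collapse = ", "))
  }
  expr <- expression[gid]
  stratum <- ifelse(expr > expr_threshold, "high", "low")

  nb <- as.integer(2 * window / bin)
  lo <- -window + (seq_len(nb) - 1L) * bin     # relative bin starts
  hi <- lo + bin
  gstr <- as.character(GenomicRanges::strand(genes))
  tss0 <- ifelse(gstr == "+", GenomicRanges::start(genes) - 1L,
                 GenomicRanges::end(genes) - 1L)

  # genomic 1-based bin windows, strand-oriented (bin k holds offsets
  # [lo_k, hi_k) in transcription direction)
  gene_idx <- rep(seq_along(genes), each = nb)
  lo_r <- rep(lo, length(genes))
  hi_r <- rep(hi, length(genes))
  t0 <- tss0[gene_idx]
  plus <- gstr[gene_idx] == "+"
  bstart <- ifelse(plus, t0 + lo_r + 1L, t0 - hi_r + 2L)
  bend <- ifelse(plus, t0 + hi_r, t0 - lo_r + 1L)
  bstart <- pmax(bstart, 1L)
  keep <- bend >= bstart
  bins_gr <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(genes))[gene_idx][keep],
    IRanges::IRanges(bstart[keep], bend[keep]))
  cnt <- rep(0L, length(gene_idx))
  cnt[keep] <- GenomicRanges::countOverlaps(bins_gr, fragments$fragments,
                                            ignore.strand = TRUE)
  rpkm_mat <- matrix(rpkm(cnt, bin, fragments$total_mapped),
                     nrow = length(genes), ncol = nb, byrow = TRUE)

  strata <- c("high", "low")
  present <- strata[strata %in% stratum]
  absent <- setdiff(strata, present)
  if (length(absent)) {
    warning(sprintf("no genes in stratum: %s; omitted",
                    paste(absent, collapse = ", ")))
  }
  prof <- t(vapply(present, function(s) {
    colMeans(rpkm_mat[stratum == s, , drop = FALSE])
  }, numeric(nb)))
  rownames(prof) <- present
  structure(list(window = window, bin = bin, bin_mid = lo + bin / 2,
                 n_genes = table(factor(stratum, levels = present)),
                 matrix = prof),
            class = "tss_profile")
}

#' @export
print.tss_profile <- function(x, ...) {
  cat(sprintf("tss_profile: +/-%d bp in %d-bp bins; strata: %s\n",
              x$window, x$bin,
              paste(sprintf("%s (n=%d)", rownames(x$matrix),
                            as.integer(x$n_genes)), collapse = ", ")))
  invisible(x)
}

#' Flatten a TSS profile to a long table
#'
#' @param profile A `tss_profile`.
#' @return Data frame with `stratum`, `bin_mid` (bp relative to the TSS,
#'   negative upstream) and `mean_rpkm`.
#' @export
tss_profile_table <- function(profile) {
  data.frame(
    stratum = rep(rownames(profile$matrix), each = length(profile$bin_mid)),
    bin_mid = rep(profile$bin_mid, nrow(profile$matrix)),
    mean_rpkm = as.vector(t(profile$matrix)),
    stringsAsFactors = FALSE)
}
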