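# The differential-modification-region procedure: merged peak regions
# quantified as input-subtracted RPKM per condition and classified by a
# pseudocounted fold change.

#' Reads per kilobase per million mapped reads
#'
#' `count * 1e9 / (region_length * library_size)`, the per-region,
#' per-library normalization applied to both IP and INPUT counts.
#'
#' @param count Fragment count(s) in the region (non-negative).
#' @param region_length Region length in bp (> 0).
#' @param library_size Total mapped fragments in the library (> 0).
#' @return RPKM value(s); vectorized over any argument.
#' @examples
#' rpkm(100, 1000, 1e7) # 10
#' @export
rpkm <- function(count, region_length, library_size) {
  if (any(region_length <= 0)) stopf("region_length must be positive")
  if (any(library_size <= 0)) stopf("library_size must be positive")
  # doubles throughout: integer length x library-size products overflow
  as.numeric(count) * 1e9 / (as.numeric(region_length) * as.numeric(library_size))
}

#' Input-subtracted region signal
#'
#' The signal of a region in one condition: IP RPKM minus INPUT RPKM,
#' floored at zero. A region whose IP does not exceed its matched input is
#' background, not negative signal; the floor keeps downstream fold changes
#' (which add a pseudocount) well defined.
#'
#' @param ip_rpkm,input_rpkm Non-negative RPKM values (vectorized).
#' @return `pmax(ip_rpkm - input_rpkm, 0)`.
#' @export
region_signal <- function(ip_rpkm, input_rpkm) {
  if (any(ip_rpkm < 0) || any(input_rpkm < 0)) {
    stopf("RPKM values must be non-negative")
  }
  pmax(ip_rpkm - input_rpkm, 0)
}

#' Classify the between-condition change of a region signal
#'
#' Computes the pseudocounted fold change
#' `(signal_c2 + pseudocount) / (signal_c1 + pseudocount)` and classifies:
#' `increased` when fold change is strictly greater than `fold_threshold`,
#' `decreased` when strictly less than `1 / fold_threshold`, otherwise
#' `unchanged`. "More than 2-fold" is strict: a region at exactly 2-fold is
#' unchanged.
#'
#' @param signal_c1,signal_c2 Non-negative signals (vectorized).
#' @param fold_threshold Fold-change threshold (> 1); default 2.
#' @param pseudocount Pseudocount added to both signals (> 0); default 1,
#'   matching a log2(signal + 1) axis transform.
#' @return A list with `fold_change` (numeric) and `change_class` (character:
#'   `"increased"`, `"decreased"`, `"unchanged"`).
#' @examples
#' classify_change(0, 3)$change_class # "increased" (fold 4)
#' classify_change(1, 3)$change_class # "unchanged" (fold exactly 2)
#' @export
classify_change <- function(signal_c1, signal_c2, fold_threshold = 2,
                            pseudocount = 1) {
  if (any(signal_c1 < 0) || any(signal_c2 < 0)) {
    stopf("signals must be non-negative")
  }
  if (fold_threshold <= 1) stopf("fold_threshold must be > 1")
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  fc <- (signal_c2 + pseudocount) / (signal_c1 + pseudocount)
  cls <- rep("unchanged", length(fc))
  cls[fc > fold_threshold] <- "increased"
  cls[fc < 1 / fold_threshold] <- "decreased"
  list(fold_change = fc, change_class = cls)
}

#' Call differential histone-modification regions for one mark
#'
#' The full procedure for one histone mark: (1) pool the peak calls of both
#' conditions and merge peaks within `max_gap` bp into one common region
#' set; (2) count IP and INPUT fragments per region in each condition and
#' normalize to RPKM; (3) take the input-subtracted signal per condition and
#' classify each region's change as increased, decreased or unchanged by the
#' `fold_threshold`-fold rule. Replicate libraries passed as lists are
#' pooled (fragments concatenated, library sizes summed) before counting.
#'
#' @param peaks_c1,peaks_c2 `GRanges` of peak calls per condition (same
#'   mark).
#' @param ip_c1,input_c1,ip_c2,input_c2 `fragment_set` objects (or lists of
#'   replicate sets to pool).
#' @param mark Mark label recorded in the output (default taken from
#'   `ip_c1`).
#' @param max_gap Peak-merge gap in bp (default 1000).
#' @param fold_threshold,pseudocount Passed to [classify_change()].
#' @return A data frame, one row per merged region, sorted by (chromosome,
#'   start): `chrom`, `start`, `end` (0-based half-open), `mark`,
#'   `n_sources`, per-condition IP/INPUT counts and RPKM, `signal_c1`,
#'   `signal_c2`, `fold_change`, `change_class`.
#' @export
call_differential_regions <- function(peaks_c1, peaks_c2,
                                      ip_c1, input_c1, ip_c2, input_c2,
                                      mark = NULL, max_gap = 1000,
                                      fold_threshold = 2, pseudocount = 1) {
  ip_c1 <- pool_fragment_sets(ip_c1)
  input_c1 <- pool_fragment_sets(input_c1)
  ip_c2 <- pool_fragment_sets(ip_c2)
  input_c2 <- pool_fragment_sets(input_c2)
  for (fs in list(ip_c1, input_c1, ip_c2, input_c2)) {
    if (fs$total_mapped == 0) stopf("empty fragment set: %s", fs$library_id)
  }
  if (is.null(mark)) mark <- ip_c1$mark

  merged <- merge_with_gap(c(GenomicRanges::granges(peaks_c1),
                             GenomicRanges::granges(peaks_c2)),
                           max_gap = max_gap)
  len <- GenomicRanges::width(merged)

  quant <- function(fs) {
    cnt <- count_overlapping(merged, fs)
    list(count = cnt, rpkm = rpkm(cnt, len, fs$total_mapped))
  }
  q_ip1 <- quant(ip_c1); q_in1 <- quant(input_c1)
  q_ip2 <- quant(ip_c2); q_in2 <- quant(input_c2)

  sig1 <- region_signal(q_ip1$rpkm, q_in1$rpkm)
  sig2 <- region_signal(q_ip2$rpkm, q_in2$rpkm)
  cls <- classify_change(sig1, sig2, fold_threshold = fold_threshold,
                         pseudocount = pseudocount)

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    mark = rep(mark, length(merged)),
    n_sources = S4Vectors::mcols(merged)$n_sources,
    ip_count_c1 = q_ip1$count, input_count_c1 = q_in1$count,
    ip_count_c2 = q_ip2$count, input_count_c2 = q_in2$count,
    ip_rpkm_c1 = q_ip1$rpkm, input_rpkm_c1 = q_in1$rpkm,
    ip_rpkm_c2 = q_ip2$rpkm, input_rpkm_c2 = q_in2$rpkm,
    signal_c1 = sig1, signal_c2 = sig2,
    fold_change = cls$fold_change, change_class = cls$change_class,
    stringsAsFactors = FALSE)
  df[order_chrom(df$chrom, df$start), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Tabulate differential-region classes
#'
#' @param regions A region-signal data frame (or a named list of them, one
#'   per mark).
#' @return A data frame with columns `mark`, `increased`, `decreased`,
#'   `unchanged`, `total`.
#' @export
diff_region_counts <- function(regions) {
  if (is.data.frame(regions)) regions <- list(regions)
  rows <- lapply(regions, function(df) {
    data.frame(mark = df$mark[1] %||% NA_character_,
               increased = sum(df$change_class == "increased"),
               decreased = sum(df$change_class == "decreased"),
               unchanged = sum(df$change_class == "unchanged"),
               total = nrow(df))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
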