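# Interval arithmetic underlying every downstream stage: gap-tolerant
# merging, disjoint-region fragment counting, and nearest-TSS assignment.

#' Merge intervals separated by at most a gap
#'
#' Pools intervals (strand-blind) and merges any two on the same chromosome
#' whose gap is at most `max_gap` bp, transitively, so the output regions are
#' pairwise separated by gaps strictly greater than `max_gap`. With the
#' default `max_gap = 1000` this is the "peaks within 1 kb are merged" rule
#' (BedTools `merge -d 1000` semantics: the gap from one interval's end to
#' the next interval's start, boundary inclusive). Intervals on different
#' chromosomes never merge.
#'
#' @param intervals A `GRanges`; may be unsorted and overlapping.
#' @param max_gap Maximum gap in bp that still merges (>= 0).
#' @return A `GRanges` sorted by (chromosome, start), strand `*`, with
#'   metadata columns `n_sources` (number of input intervals merged) and
#'   `source_ids` (a `CharacterList` of their names, where the input had a
#'   `name` column).
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(101, 901, 2501), c(200, 1000, 2600)))
#' merge_with_gap(gr, max_gap = 1000) # first two merge (gap 700), third not
#' @export
merge_with_gap <- function(intervals, max_gap = 1000) {
  if (!methods::is(intervals, "GRanges")) stopf("intervals must be a GRanges")
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0) {
    stopf("max_gap must be a single non-negative number")
  }
  if (length(intervals) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      n_sources = integer(0), source_ids = IRanges::CharacterList())
    return(out)
  }
  red <- GenomicRanges::reduce(intervals, min.gapwidth = max_gap + 1,
                               ignore.strand = TRUE, with.revmap = TRUE)
  red <- sort_regions(red)
  revmap <- S4Vectors::mcols(red)$revmap
  nm <- if ("name" %in% names(S4Vectors::mcols(intervals))) {
    as.character(S4Vectors::mcols(intervals)$name)
  } else {
    rep(NA_character_, length(intervals))
  }
  src <- IRanges::CharacterList(lapply(revmap, function(i) nm[i][!is.na(nm[i])]))
  out <- GenomicRanges::granges(red)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    n_sources = lengths(revmap), source_ids = src)
  out
}

#' Count fragments overlapping disjoint regions
#'
#' Counts, for each region, the fragments overlapping it by at least 1 bp
#' (strand-blind, no midpoint or fraction rule). Regions must be pairwise
#' non-overlapping per chromosome, as produced by [merge_with_gap()]; a
#' fragment long enough to span the gap between two regions counts once in
#' each.
#'
#' @param regions A `GRanges` of pairwise disjoint regions.
#' @param fragments A `fragment_set` or a `GRanges` of fragments.
#' @return Integer vector of counts, one per region, in region order.
#' @export
count_overlapping <- function(regions, fragments) {
  if (!methods::is(regions, "GRanges")) stopf("regions must be a GRanges")
  if (methods::is(fragments, "fragment_set")) fragments <- fragments$fragments
  if (!GenomicRanges::isDisjoint(regions, ignore.strand = TRUE)) {
    stopf("regions must be pairwise non-overlapping")
  }
  GenomicRanges::countOverlaps(regions, fragments, minoverlap = 1L,
                               ignore.strand = TRUE)
}

#' Assign each region to the gene with the nearest TSS
#'
#' Measures, for every region, the distance from the region midpoint to each
#' gene's TSS on the same chromosome and returns the minimizing gene. The
#' distance is signed by the gene's transcription orientation: positive when
#' the midpoint lies downstream of the TSS (inside or past the gene),
#' negative when upstream, 0 when the midpoint sits on the TSS. Ties on
#' |distance| break to the lexicographically smallest `gene_id`. Regions on
#' a chromosome without genes get `NA` (no cross-chromosome assignment).
#'
#' @param regions A `GRanges`.
#' @param gene_models A `gene_models` object (see [read_gene_models()]).
#' @return A data frame with one row per region: `gene_id` (character, `NA`
#'   if unassignable) and `distance` (integer bp, signed).
#' @export
nearest_tss <- function(regions, gene_models) {
  if (!methods::is(regions, "GRanges")) stopf("regions must be a GRanges")
  genes <- gene_models$genes
  if (length(genes) == 0) stopf("gene_models contains no genes")

  out_gene <- rep(NA_character_, length(regions))
  out_dist <- rep(NA_integer_, length(regions))
  if (length(regions) == 0) {
    return(data.frame(gene_id = out_gene, distance = out_dist))
  }

  mid0 <- midpoint0(regions)
  # TSS as a 0-based coordinate: start0 for '+', end0 - 1 for '-'
  gstr <- as.character(GenomicRanges::strand(genes))
  tss0_all <- ifelse(gstr == "+", GenomicRanges::start(genes) - 1L,
                     GenomicRanges::end(genes) - 1L)
  gid_all <- S4Vectors::mcols(genes)$gene_id
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  rchrom <- as.character(GenomicRanges::seqnames(regions))

  for (ch in unique(rchrom)) {
    ri <- which(rchrom == ch)
    gi <- which(gchrom == ch)
    if (!length(gi)) next
    ord <- order(tss0_all[gi], gid_all[gi], method = "radix")
    t0 <- tss0_all[gi][ord]
    gids <- gid_all[gi][ord]
    strs <- gstr[gi][ord]
    n <- length(t0)
    m <- mid0[ri]

    # index of the rightmost TSS <= midpoint (0 if none)
    i <- findInterval(m, t0)
    has_l <- i >= 1L
    has_r <- i < n
    dl <- ifelse(has_l, m - t0[pmax(i, 1L)], NA_integer_)
    dr <- ifelse(has_r, t0[pmin(i + 1L, n)] - m, NA_integer_)
    dmin <- pmin(dl, dr, na.rm = TRUE)

    # first (lexicographically smallest gene_id) gene at a given TSS value
    first_at <- function(v) findInterval(v - 0.5, t0) + 1L
    il <- ifelse(has_l & !is.na(dl) & dl == dmin, first_at(m - dmin), NA_integer_)
    ir <- ifelse(has_r & !is.na(dr) & dr == dmin, first_at(m + dmin), NA_integer_)
    gl <- ifelse(is.na(il), NA_character_, gids[il])
    gr_ <- ifelse(is.na(ir), NA_character_, gids[ir])
    pick_left <- !is.na(gl) & (is.na(gr_) | gl <= gr_)
    idx <- ifelse(pick_left, il, ir)

    chosen_tss <- t0[idx]
    chosen_str <- strs[idx]
    d_signed <- ifelse(chosen_str == "+", m - chosen_tss, chosen_tss - m)
    out_gene[ri] <- gids[idx]
    out_dist[ri] <- as.integer(d_signed)
  }
  data.frame(gene_id = out_gene, distance = out_dist)
}
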