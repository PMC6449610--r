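# Internal helpers shared across modules.

# Run code with a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded up (away from zero),
#' the convention used for all reported percentages, rather than base R's
#' round-half-to-even.
#'
#' @param x Numeric vector (non-negative in all reporting uses).
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(93.4938, 1) # 93.5
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Stop with a consistent message prefix naming the offending argument.
stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Coerce a region table (chrom/start/end in 0-based half-open coordinates,
# as written by write_regions_tsv) or a GRanges to a GRanges.
as_region_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  if (is.data.frame(x)) {
    req <- c("chrom", "start", "end")
    if (!all(req %in% names(x))) {
      stopf("region table must have columns %s", paste(req, collapse = ", "))
    }
    return(GenomicRanges::GRanges(x$chrom,
                                  IRanges::IRanges(x$start + 1L, x$end)))
  }
  stopf("cannot interpret object of class '%s' as regions", class(x)[1])
}

# 0-based midpoint of each range: floor((start0 + end0) / 2) where
# [start0, end0) is the half-open form of the 1-based closed GRanges.
midpoint0 <- function(gr) {
  (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L
}

# Sort a GRanges by (chromosome name, start) with natural chromosome ordering.
sort_regions <- function(gr) {
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
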