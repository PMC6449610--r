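# FragmentSet: a sequencing library reduced to aligned fragment intervals.

#' Construct a fragment set
#'
#' Bundles the aligned fragments of one ChIP-seq library (IP or INPUT) with
#' the metadata needed for RPKM normalization. `total_mapped` is always the
#' number of fragments in the set after filtering; it is the library size
#' used as the RPKM denominator.
#'
#' @param fragments A `GRanges` of fragment intervals (each at least 1 bp).
#' @param library_id Library label.
#' @param role `"IP"` (immunoprecipitated) or `"INPUT"` (control).
#' @param mark Histone mark of the IP antibody: `"H3K4me3"`, `"H3K27ac"`, or
#'   `"none"` for an INPUT library shared across marks.
#' @param condition Condition label (e.g. `"c1"`, `"c2"`).
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, library_id = "lib",
                         role = c("IP", "INPUT"),
                         mark = c("H3K4me3", "H3K27ac", "none"),
                         condition = "c1") {
  role <- match.arg(role)
  mark <- match.arg(mark)
  if (!methods::is(fragments, "GRanges")) {
    stopf("fragments must be a GRanges")
  }
  structure(list(fragments = fragments,
                 library_id = library_id,
                 role = role,
                 mark = mark,
                 condition = condition,
                 total_mapped = length(fragments)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set %s [%s, %s, %s]: %d fragments\n",
              x$library_id, x$role, x$mark, x$condition, x$total_mapped))
  invisible(x)
}

#' Read a fragment BED file into a fragment set
#'
#' @param path BED file of fragment intervals.
#' @inheritParams fragment_set
#' @param ... Passed to [read_bed()].
#' @return A `fragment_set`.
#' @export
read_fragments_bed <- function(path, library_id = basename(path),
                               role = c("IP", "INPUT"),
                               mark = c("H3K4me3", "H3K27ac", "none"),
                               condition = "c1", ...) {
  fragment_set(read_bed(path, ...), library_id = library_id, role = role,
               mark = mark, condition = condition)
}

#' Pool replicate fragment sets
#'
#' Concatenates the fragments of replicate libraries into a single set;
#' library sizes sum. All sets must share role, mark and condition. This
#' mirrors pooling replicates before quantification.
#'
#' @param sets A list of `fragment_set` objects (a single set passes
#'   through).
#' @return One pooled `fragment_set`.
#' @export
pool_fragment_sets <- function(sets) {
  if (methods::is(sets, "fragment_set")) return(sets)
  if (!length(sets)) stopf("no fragment sets to pool")
  stopifnot(all(vapply(sets, methods::is, logical(1), "fragment_set")))
  meta <- unique(t(vapply(sets, function(s) c(s$role, s$mark, s$condition),
                          character(3))))
  if (nrow(meta) != 1) {
    stopf("cannot pool fragment sets with differing role/mark/condition")
  }
  frags <- do.call(c, lapply(sets, `[[`, "fragments"))
  fragment_set(frags,
               library_id = paste(vapply(sets, `[[`, character(1),
                                         "library_id"), collapse = "+"),
               role = meta[1, 1], mark = meta[1, 2], condition = meta[1, 3])
}
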