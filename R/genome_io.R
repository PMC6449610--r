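# Readers and writers for the interchange formats the pipeline touches.
#
# Internal coordinates follow the Bioconductor convention: GRanges, 1-based,
# closed. BED input (0-based, half-open) is converted at the boundary; GTF
# input (1-based, closed) passes through unchanged; written BED and region
# tables convert back to 0-based half-open starts.

#' Read a BED or narrowPeak file of genomic intervals
#'
#' Reads BED3/BED6 and narrowPeak (10-column) files into a `GRanges`. BED's
#' 0-based half-open coordinates become 1-based closed on import. Columns
#' 4--6, when present, populate the `name` and `score` metadata columns and
#' the strand; extra narrowPeak columns are ignored. Input row order is
#' preserved.
#'
#' Chromosome names are taken verbatim: `"chr1"` and `"1"` are different
#' sequences. Supply `chrom_alias` (named character vector, `old = new`) to
#' rename on import when two files disagree.
#'
#' @param path Path to an existing, tab-separated BED-like file.
#' @param chrom_alias Optional named character vector mapping chromosome
#'   names as found in the file to the names used internally.
#' @return A `GRanges` with metadata columns `name` (character) and `score`
#'   (numeric); `NA` where the file omits them.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tpk1\t50\t+", tf)
#' read_bed(tf)
#' @export
read_bed <- function(path, chrom_alias = NULL) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  empty <- GenomicRanges::GRanges(name = character(0), score = numeric(0))
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE,
                          data.table = FALSE, quote = "")
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) < 3) stopf("BED file %s has fewer than 3 columns", path)

  chrom <- dt[[1]]
  start0 <- suppressWarnings(as.integer(dt[[2]]))
  end0 <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) {
    stopf("BED file %s: non-integer coordinates at line %d", path, bad[1])
  }
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad)) {
    stopf("BED file %s: invalid interval (start >= end or start < 0) at line %d",
          path, bad[1])
  }

  name <- if (ncol(dt) >= 4) dt[[4]] else rep(NA_character_, nrow(dt))
  name[!is.na(name) & name %in% c(".", "")] <- NA_character_
  score <- if (ncol(dt) >= 5) {
    s <- dt[[5]]
    s[s == "." | s == ""] <- NA_character_
    as.numeric(s)
  } else {
    rep(NA_real_, nrow(dt))
  }
  strand <- if (ncol(dt) >= 6) dt[[6]] else rep(".", nrow(dt))
  strand[is.na(strand) | strand == ""] <- "."
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad)) {
    stopf("BED file %s: unknown strand '%s' at line %d",
          path, strand[bad[1]], bad[1])
  }
  strand[strand == "."] <- "*"

  if (!is.null(chrom_alias)) {
    hit <- chrom %in% names(chrom_alias)
    chrom[hit] <- unname(chrom_alias[chrom[hit]])
  }

  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                         strand = strand, name = name, score = score)
}

#' Write intervals as BED6
#'
#' Inverse of [read_bed()]: 1-based closed `GRanges` coordinates are written
#' as 0-based half-open BED columns, preserving order, name, score and
#' strand (`*` becomes `.`; missing name/score become `.`).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  name <- if ("name" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$name)
  } else {
    rep(NA_character_, length(gr))
  }
  score <- if ("score" %in% names(S4Vectors::mcols(gr))) {
    S4Vectors::mcols(gr)$score
  } else {
    rep(NA_real_, length(gr))
  }
  name[is.na(name)] <- "."
  score_chr <- ifelse(is.na(score), ".", format(score, trim = TRUE,
                                                scientific = FALSE))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, score = score_chr, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Parses GTF-style annotation (9 columns, 1-based closed, attributes with
#' `gene_id`) into a `gene_models` object: one record per distinct gene with
#' its body, strand, TSS/TTS, and any exon and UTR features grouped under it.
#'
#' The TSS is the 5' end of the gene body in transcription orientation (the
#' start for `+` genes, the end for `-` genes) and the TTS the 3' end. A
#' gene referenced only by its features (no `gene` record) gets a body
#' synthesized as the span of those features, with a warning. Genes must be
#' stranded; an unstranded gene record is an error.
#'
#' @param path Path to a GTF file.
#' @return An object of class `gene_models`: a list with elements
#'   `genes` (a stranded `GRanges` with metadata columns `gene_id`, `tss`,
#'   `tts`, both 1-based positions), `exons`, `utr5`, `utr3` (each a
#'   `GRangesList` indexed by `gene_id`; possibly empty per gene).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  if (!"gene_id" %in% names(S4Vectors::mcols(gr))) {
    stopf("GTF file %s has no gene_id attributes", path)
  }
  type <- as.character(S4Vectors::mcols(gr)$type)
  gid <- as.character(S4Vectors::mcols(gr)$gene_id)
  if (anyNA(gid)) stopf("GTF file %s: feature without gene_id", path)

  is_gene <- type == "gene"
  gene_ids <- unique(gid)
  genes <- gr[is_gene]
  gene_gid <- gid[is_gene]
  if (anyDuplicated(gene_gid)) {
    stopf("GTF file %s: duplicated gene records", path)
  }

  orphan <- setdiff(gene_ids, gene_gid)
  if (length(orphan)) {
    warning(sprintf(
      "%d gene_id(s) have no gene record; synthesizing bodies from feature spans: %s",
      length(orphan), paste(utils::head(orphan, 5), collapse = ", ")))
    for (g in orphan) {
      feats <- gr[gid == g]
      chr <- unique(as.character(GenomicRanges::seqnames(feats)))
      str_g <- unique(as.character(GenomicRanges::strand(feats)))
      if (length(chr) != 1 || length(str_g) != 1) {
        stopf("features of gene %s span multiple chromosomes/strands", g)
      }
      body <- GenomicRanges::GRanges(
        chr,
        IRanges::IRanges(min(GenomicRanges::start(feats)),
                         max(GenomicRanges::end(feats))),
        strand = str_g)
      S4Vectors::mcols(body) <- S4Vectors::mcols(feats[1])
      genes <- c(genes, body)
      gene_gid <- c(gene_gid, g)
    }
  }

  str <- as.character(GenomicRanges::strand(genes))
  if (any(str == "*")) {
    stopf("gene(s) without strand: %s",
          paste(utils::head(gene_gid[str == "*"], 5), collapse = ", "))
  }
  # keep first-appearance order of gene_ids
  ord <- match(gene_ids, gene_gid)
  genes <- genes[ord]
  str <- str[ord]

  tss <- ifelse(str == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  tts <- ifelse(str == "+", GenomicRanges::end(genes),
                GenomicRanges::start(genes))
  out_genes <- GenomicRanges::granges(genes)
  S4Vectors::mcols(out_genes) <- S4Vectors::DataFrame(
    gene_id = gene_ids, tss = as.integer(tss), tts = as.integer(tts))

  grab <- function(what) {
    sub <- gr[type %in% what]
    sub_gid <- factor(gid[type %in% what], levels = gene_ids)
    S4Vectors::split(GenomicRanges::granges(sub), sub_gid)
  }
  exons <- grab("exon")
  utr5 <- grab(c("five_prime_utr", "5UTR"))
  utr3 <- grab(c("three_prime_utr", "3UTR"))

  # exons must lie within their gene body
  ex_flat <- unlist(exons)
  if (length(ex_flat)) {
    owner <- out_genes[match(names(ex_flat), gene_ids)]
    contained <- as.character(GenomicRanges::seqnames(ex_flat)) ==
      as.character(GenomicRanges::seqnames(owner)) &
      GenomicRanges::start(ex_flat) >= GenomicRanges::start(owner) &
      GenomicRanges::end(ex_flat) <= GenomicRanges::end(owner)
    if (!all(contained)) {
      stopf("exon outside its gene body (gene %s)",
            names(ex_flat)[which(!contained)[1]])
    }
  }

  structure(list(genes = out_genes, exons = exons, utr5 = utr5, utr3 = utr3),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d sequence(s), %d exons\n",
              length(x$genes),
              length(GenomeInfoDb::seqlevelsInUse(x$genes)),
              length(unlist(x$exons))))
  invisible(x)
}

# column order of the on-disk region-signal table
region_tsv_columns <- function() {
  c("chrom", "start", "end", "mark", "n_sources",
    "ip_count_c1", "input_count_c1", "ip_count_c2", "input_count_c2",
    "ip_rpkm_c1", "input_rpkm_c1", "ip_rpkm_c2", "input_rpkm_c2",
    "signal_c1", "signal_c2", "fold_change", "change_class")
}

#' Write a region-signal table to TSV
#'
#' Writes the output of [call_differential_regions()] as a tab-separated,
#' UTF-8, Unix-newline table with a header, one row per merged region,
#' sorted by (chromosome, start). Coordinates are written 0-based half-open
#' (BED-like starts) so the table can be intersected with BED tooling.
#'
#' @param regions Region-signal data frame (see
#'   [call_differential_regions()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_regions_tsv()] for the inverse.
#' @export
write_regions_tsv <- function(regions, path) {
  cols <- region_tsv_columns()
  missing_cols <- setdiff(cols, names(regions))
  if (length(missing_cols)) {
    stopf("region table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  regions <- regions[order_chrom(regions$chrom, regions$start), cols,
                     drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con, sep = "\n")
  if (nrow(regions)) {
    lines <- do.call(paste, c(lapply(regions, function(col) {
      if (is.numeric(col) && !is.integer(col)) {
        format(col, trim = TRUE, scientific = FALSE, digits = 15)
      } else {
        as.character(col)
      }
    }), sep = "\t"))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a region-signal table written by [write_regions_tsv()]
#'
#' @param path Path to the TSV.
#' @return The region-signal data frame, columns typed as written.
#' @export
read_regions_tsv <- function(path) {
  if (!file.exists(path)) stopf("region table not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c(chrom = "character", mark = "character",
                                  change_class = "character"))
  int_cols <- c("start", "end", "n_sources", "ip_count_c1", "input_count_c1",
                "ip_count_c2", "input_count_c2")
  for (cc in intersect(int_cols, names(df))) df[[cc]] <- as.integer(df[[cc]])
  df
}

# natural ordering of chromosome names (chr2 before chr10), then start
order_chrom <- function(chrom, start) {
  lev <- GenomeInfoDb::sortSeqlevels(unique(chrom))
  order(match(chrom, lev), start)
}
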