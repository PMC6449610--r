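# Brute-force oracles and small fixture builders, independent of the
# package's implementation paths.

# GRanges from 0-based half-open coordinates (BED-like), for readable tests
gr0 <- function(chrom, start0, end0, strand = "*", name = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  gr
}

df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# transitive-closure merge: repeatedly fuse any two intervals on the same
# chromosome whose gap is <= max_gap, until nothing changes
brute_merge <- function(df, max_gap) {
  rows <- split(df, seq_len(nrow(df)))
  repeat {
    fused <- FALSE
    for (i in seq_along(rows)) {
      if (is.null(rows[[i]])) next
      for (j in seq_along(rows)) {
        if (i == j || is.null(rows[[j]]) || is.null(rows[[i]])) next
        a <- rows[[i]]; b <- rows[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(a$start0, b$start0) - min(a$end0, b$end0)
        if (gap <= max_gap) {
          rows[[i]] <- data.frame(chrom = a$chrom,
                                  start0 = min(a$start0, b$start0),
                                  end0 = max(a$end0, b$end0))
          rows[[j]] <- NULL
          fused <- TRUE
          break
        }
      }
      if (fused) break
    }
    if (!fused) break
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out[order(out$chrom, out$start0), , drop = FALSE]
}

# all-pairs overlap count (>= 1 bp, half-open coords)
brute_count <- function(regions_df, frags_df) {
  vapply(seq_len(nrow(regions_df)), function(i) {
    r <- regions_df[i, ]
    sum(frags_df$chrom == r$chrom &
          frags_df$start0 < r$end0 &
          frags_df$end0 > r$start0)
  }, numeric(1))
}

# minimum |midpoint - TSS| over all same-chromosome genes, lexicographic
# gene_id tie-break, orientation-signed distance
brute_nearest_tss <- function(mid0, chrom, genes_df) {
  g <- genes_df[genes_df$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, distance = NA_integer_))
  d <- abs(mid0 - g$tss0)
  best <- which(d == min(d))
  best <- best[order(g$gene_id[best])][1]
  signed <- if (g$strand[best] == "+") mid0 - g$tss0[best] else g$tss0[best] - mid0
  list(gene_id = g$gene_id[best], distance = as.integer(signed))
}

rand_intervals <- function(n, n_chroms = 2, max_pos = 10000, max_len = 400) {
  chrom <- sample(sprintf("chr%d", seq_len(n_chroms)), n, replace = TRUE)
  s0 <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = chrom, start0 = s0, end0 = s0 + len,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) gr0(df$chrom, df$start0, df$end0)

# gene_models built through the GTF reader from a compact spec:
# data.frame(gene_id, chrom, start0, end0, strand) plus optional features
toy_gene_models <- function(genes, features = NULL) {
  lines <- sprintf('%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                   genes$chrom, genes$start0 + 1, genes$end0, genes$strand,
                   genes$gene_id)
  if (!is.null(features)) {
    lines <- c(lines,
               sprintf('%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                       features$chrom, features$type, features$start0 + 1,
                       features$end0, features$strand, features$gene_id))
  }
  tf <- tempfile(fileext = ".gtf")
  writeLines(lines, tf)
  on.exit(unlink(tf))
  read_gene_models(tf)
}

# fragment_set from 0-based coordinate vectors
make_fs <- function(chrom, start0, end0, role = "IP", mark = "H3K4me3",
                    condition = "c1", library_id = "t") {
  fragment_set(gr0(chrom, start0, end0), library_id = library_id,
               role = role, mark = mark, condition = condition)
}

# uniformly spaced fragments of fixed length covering [0, genome_len)
uniform_fs <- function(chrom = "chr1", genome_len = 1e5, step = 50,
                       frag_len = 100, ...) {
  s0 <- seq(0, genome_len - frag_len, by = step)
  make_fs(chrom, s0, s0 + frag_len, ...)
}

# compact simulation config used by most pipeline-level tests
small_sim_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_chroms = 2, chrom_length = 6e5, n_genes = 60,
               n_enriched_per_mark = 60, background_rate = 0.02,
               frac_de_up = 0.2, frac_de_down = 0.2)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# the fixed-seed 500-region recovery simulation shared by the acceptance
# checks: true folds >= 4, expected IP fragments per enriched region
# 0.015 * 1000 * 4 = 60 >= 50
recovery_sim_config <- function(seed = 20240501) {
  sim_config(seed = seed, n_chroms = 3, chrom_length = 4e6, n_genes = 150,
             n_enriched_per_mark = 500, region_width = 1000,
             background_rate = 0.015, fold_changed_min = 4,
             fold_changed_max = 8, frac_regions_increased = 0.4,
             frac_regions_decreased = 0.2)
}

# cache expensive shared fixtures across test files within one run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

recovery_run <- function() {
  cached("recovery_run", {
    sim <- simulate_dataset(recovery_sim_config())
    fr <- sim$fragments$H3K4me3
    called <- call_differential_regions(
      sim$peaks$H3K4me3$c1, sim$peaks$H3K4me3$c2,
      fr$c1$ip, fr$c1$input, fr$c2$ip, fr$c2$input, mark = "H3K4me3")
    list(sim = sim, called = called)
  })
}
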