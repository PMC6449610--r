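# Synthetic-data generator: produces every pipeline input (gene models,
# peak calls, IP/INPUT fragment libraries, DE and expression tables) with
# known per-gene and per-region ground truth.

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic dataset. Defaults
#' describe a compact two-condition study: a few megabase-scale chromosomes,
#' non-overlapping stranded gene models, two histone marks with enriched
#' regions whose IP fragment counts follow Poisson(background x length x
#' fold), condition-specific enrichment folds for truly increased/decreased
#' regions, peak calls over enriched regions with boundary jitter, and a DE
#' table with known up/down truth. `coupling_prob` is the probability that a
#' truly up-regulated gene hosts an H3K4me3-increased region within 1 kb of
#' its TSS, tying mark gain to up-regulation.
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param n_genes Total genes, placed without overlap (error if they do not
#'   fit).
#' @param gene_length_min,gene_length_max Uniform gene-length range (bp).
#' @param frac_de_up,frac_de_down Fractions of genes truly up/down.
#' @param n_enriched_per_mark Enriched regions per mark (includes the
#'   promoter-coupled ones).
#' @param region_width Width of each enriched region (bp).
#' @param frac_regions_increased,frac_regions_decreased Fractions of each
#'   mark's regions that truly increase/decrease (the rest are enriched but
#'   flat).
#' @param fold_changed_min,fold_changed_max Uniform range of the enrichment
#'   fold in the changed condition (>= 4 keeps signals well separated).
#' @param fold_flat Enrichment fold of flat regions in both conditions.
#' @param background_rate Background fragment rate (fragments per bp per
#'   library).
#' @param fragment_length Fragment length (bp, fixed).
#' @param coupling_prob Probability a truly up gene gets a promoter-proximal
#'   H3K4me3-increased region.
#' @param peak_jitter Maximum absolute jitter (bp) applied to each emitted
#'   peak boundary.
#' @param n_samples_c1,n_samples_c2 RNA-seq samples per condition.
#' @param nb_dispersion Negative-binomial dispersion of simulated counts.
#' @param de_alpha Adjusted-p threshold the simulated padj values respect.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L, chrom_length = 2e6,
                       n_genes = 300L,
                       gene_length_min = 2000, gene_length_max = 8000,
                       frac_de_up = 0.15, frac_de_down = 0.15,
                       n_enriched_per_mark = 300L,
                       region_width = 1000,
                       frac_regions_increased = 0.4,
                       frac_regions_decreased = 0.2,
                       fold_changed_min = 4, fold_changed_max = 8,
                       fold_flat = 5,
                       background_rate = 0.02,
                       fragment_length = 200,
                       coupling_prob = 0.7,
                       peak_jitter = 200,
                       n_samples_c1 = 6L, n_samples_c2 = 4L,
                       nb_dispersion = 0.05,
                       de_alpha = 0.01) {
  cfg <- as.list(environment())
  probs <- c(frac_de_up, frac_de_down, frac_regions_increased,
             frac_regions_decreased, coupling_prob)
  if (any(probs < 0 | probs > 1)) stopf("fractions/probabilities must be in [0, 1]")
  if (frac_de_up + frac_de_down > 1) stopf("DE fractions exceed 1")
  if (frac_regions_increased + frac_regions_decreased > 1) {
    stopf("region class fractions exceed 1")
  }
  if (background_rate < 0) stopf("background_rate must be >= 0")
  if (fold_changed_min < 1 || fold_changed_max < fold_changed_min) {
    stopf("invalid fold range")
  }
  if (gene_length_max < gene_length_min) stopf("invalid gene length range")
  structure(cfg, class = "sim_config")
}

# non-overlapping gene placement; error when the genome cannot hold them
place_genes <- function(cfg) {
  margin <- 10000
  min_gap <- 8000
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  rows <- vector("list", cfg$n_chroms)
  gi <- 0L
  for (ch in seq_len(cfg$n_chroms)) {
    k <- per_chrom[ch]
    if (k == 0) next
    len <- round(runif(k, cfg$gene_length_min, cfg$gene_length_max))
    slack <- cfg$chrom_length - 2 * margin - sum(len) - (k - 1) * min_gap
    if (slack < 0) {
      stopf("cannot place %d genes on a %g-bp chromosome", k, cfg$chrom_length)
    }
    extra <- if (k > 0) {
      e <- runif(k + 1)
      floor(slack * e / sum(e))
    } else {
      0
    }
    gaps <- c(margin + extra[1], min_gap + extra[-1][seq_len(k - 1)])
    start0 <- cumsum(gaps) + c(0, cumsum(len))[seq_len(k)]
    rows[[ch]] <- data.frame(chrom = sprintf("chr%d", ch),
                             start0 = start0, end0 = start0 + len,
                             strand = sample(c("+", "-"), k, replace = TRUE))
    gi <- gi + k
  }
  genes <- do.call(rbind, rows)
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes
}

# GTF text for the simulated gene models (gene/exon/UTR features, 3 exons)
gene_models_gtf <- function(genes) {
  lines <- character(0)
  attr_of <- function(g) sprintf('gene_id "%s";', g)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s1 <- g$start0 + 1  # 1-based closed
    e1 <- g$end0
    len <- e1 - s1 + 1
    # three exons at fixed fractional positions of the body
    b <- round(c(0, 0.2, 0.45, 0.6, 0.8, 1) * len)
    ex <- cbind(s1 + c(b[1], b[3], b[5]), s1 + c(b[2], b[4], b[6]) - 1)
    ex[ex[, 2] > e1, 2] <- e1
    utr_len <- min(200, len %/% 10)
    if (g$strand == "+") {
      utr5 <- c(s1, s1 + utr_len - 1)
      utr3 <- c(e1 - utr_len + 1, e1)
    } else {
      utr5 <- c(e1 - utr_len + 1, e1)
      utr3 <- c(s1, s1 + utr_len - 1)
    }
    feat <- function(type, s, e) {
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s, e, g$strand, attr_of(g$gene_id))
    }
    lines <- c(lines,
               feat("gene", s1, e1),
               feat("exon", ex[1, 1], ex[1, 2]),
               feat("exon", ex[2, 1], ex[2, 2]),
               feat("exon", ex[3, 1], ex[3, 2]),
               feat("five_prime_utr", utr5[1], utr5[2]),
               feat("three_prime_utr", utr3[1], utr3[2]))
  }
  lines
}

#' Simulate a full synthetic dataset
#'
#' Generates gene models, per-mark enriched regions with condition-specific
#' enrichment folds, IP/INPUT fragment libraries, peak calls, a counts
#' matrix, a DE table and normalized expression, together with the ground
#' truth behind each of them. With `out_dir` set, all inputs are also
#' written in their interchange formats (GTF, BED, TSV); two runs with the
#' same config produce byte-identical files.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory to write the files into (created if
#'   needed).
#' @return A list: `gene_models`, `peaks` (list mark -> condition ->
#'   `GRanges`), `fragments` (list mark -> condition -> list(ip, input) of
#'   `fragment_set`s), `counts` (matrix), `de` (data frame), `expr`
#'   (normalized matrix), `truth_genes`, `truth_regions` (data frames),
#'   `config`, and `files` (named paths when `out_dir` was given).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(methods::is(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config, out_dir))
}

simulate_dataset_impl <- function(cfg, out_dir) {
  marks <- c("H3K4me3", "H3K27ac")
  genes <- place_genes(cfg)

  # --- gene truth: direction, log2fc, padj, expression baseline
  n <- nrow(genes)
  n_up <- round(cfg$frac_de_up * n)
  n_down <- round(cfg$frac_de_down * n)
  dir_vec <- sample(rep(c("up", "down", "ns"),
                        c(n_up, n_down, n - n_up - n_down)))
  log2fc <- ifelse(dir_vec == "up", runif(n, 1, 3),
                   ifelse(dir_vec == "down", -runif(n, 1, 3),
                          rnorm(n, 0, 0.2)))
  padj <- ifelse(dir_vec == "ns",
                 runif(n, cfg$de_alpha, 1),
                 runif(n, 1e-8, cfg$de_alpha * (1 - 1e-9)))
  tss0 <- ifelse(genes$strand == "+", genes$start0, genes$end0 - 1)

  # --- enriched regions per mark: coupled promoter regions first, the rest
  # on a spaced intergenic-ish grid so truth regions never merge together
  region_rows <- list()
  coupled <- logical(n)
  half <- cfg$region_width / 2
  for (mk in marks) {
    k <- cfg$n_enriched_per_mark
    centers <- numeric(0); chroms <- character(0)
    cls <- character(0); coupled_gene <- character(0)
    if (mk == "H3K4me3") {
      up_idx <- which(dir_vec == "up")
      is_coupled <- runif(length(up_idx)) < cfg$coupling_prob
      coupled[up_idx[is_coupled]] <- TRUE
      ci <- up_idx[is_coupled]
      off <- round(runif(length(ci), -600, 600))
      centers <- tss0[ci] + off
      chroms <- genes$chrom[ci]
      cls <- rep("increased", length(ci))
      coupled_gene <- genes$gene_id[ci]
    }
    n_rest <- k - length(centers)
    if (n_rest < 0) stopf("n_enriched_per_mark too small for coupled regions")
    # candidate grid away from chromosome ends and from coupled centers
    cand <- expand.grid(chrom = sprintf("chr%d", seq_len(cfg$n_chroms)),
                        pos = seq(20000, cfg$chrom_length - 20000, by = 5000),
                        stringsAsFactors = FALSE)
    # keep candidates >= 4 kb from any TSS and any already-placed center
    keep <- rep(TRUE, nrow(cand))
    for (ch in unique(cand$chrom)) {
      ci2 <- which(cand$chrom == ch)
      occ <- c(tss0[genes$chrom == ch], centers[chroms == ch],
               if (length(region_rows))
                 unlist(lapply(region_rows, function(r)
                   r$center[r$chrom == ch])))
      if (length(occ)) {
        d <- vapply(cand$pos[ci2],
                    function(p) min(abs(p - occ)), numeric(1))
        keep[ci2] <- d >= 4000
      }
    }
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) < n_rest) stopf("not enough room for enriched regions")
    pick <- sample(nrow(cand), n_rest)
    centers <- c(centers, cand$pos[pick])
    chroms <- c(chroms, cand$chrom[pick])
    n_inc_rest <- max(round(cfg$frac_regions_increased * k) - sum(cls == "increased"), 0)
    n_dec <- round(cfg$frac_regions_decreased * k)
    n_flat <- n_rest - n_inc_rest - n_dec
    if (n_flat < 0) stopf("region class fractions inconsistent with coupling")
    cls <- c(cls, sample(rep(c("increased", "decreased", "flat"),
                             c(n_inc_rest, n_dec, n_flat))))
    coupled_gene <- c(coupled_gene, rep(NA_character_, n_rest))

    fold_hi <- runif(k, cfg$fold_changed_min, cfg$fold_changed_max)
    f1 <- ifelse(cls == "increased", 1,
                 ifelse(cls == "decreased", fold_hi, cfg$fold_flat))
    f2 <- ifelse(cls == "increased", fold_hi,
                 ifelse(cls == "decreased", 1, cfg$fold_flat))
    region_rows[[mk]] <- data.frame(
      region_id = sprintf("%s_r%04d", mk, seq_len(k)),
      mark = mk, chrom = chroms,
      start0 = round(centers - half), end0 = round(centers + half),
      center = centers, true_class = cls,
      fold_c1 = f1, fold_c2 = f2,
      coupled_gene = coupled_gene,
      stringsAsFactors = FALSE)
  }
  truth_regions <- do.call(rbind, region_rows)
  rownames(truth_regions) <- NULL

  # --- fragment libraries: background Poisson everywhere + Poisson extra
  # fragments in enriched regions at (fold - 1) x background
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  frag_lib <- function(mark, cond, role) {
    mids <- list(); chs <- list()
    for (ch in chrom_names) {
      nbg <- rpois(1, cfg$background_rate * cfg$chrom_length)
      mids[[ch]] <- round(runif(nbg, 1, cfg$chrom_length))
      chs[[ch]] <- rep(ch, nbg)
    }
    if (role == "IP") {
      tr <- truth_regions[truth_regions$mark == mark, , drop = FALSE]
      fold <- if (cond == "c1") tr$fold_c1 else tr$fold_c2
      extra <- rpois(nrow(tr), cfg$background_rate * cfg$region_width *
                       pmax(fold - 1, 0))
      for (i in which(extra > 0)) {
        mids[[length(mids) + 1]] <- round(runif(extra[i], tr$start0[i] + 1,
                                                tr$end0[i]))
        chs[[length(chs) + 1]] <- rep(tr$chrom[i], extra[i])
      }
    }
    mid <- unlist(mids, use.names = FALSE)
    ch <- unlist(chs, use.names = FALSE)
    s1 <- pmax(mid - cfg$fragment_length %/% 2, 1)
    e1 <- pmin(s1 + cfg$fragment_length - 1, cfg$chrom_length)
    gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(s1, e1))
    fragment_set(gr, library_id = sprintf("%s_%s_%s", mark, cond, role),
                 role = role, mark = if (role == "IP") mark else "none",
                 condition = cond)
  }
  fragments <- lapply(setNames(marks, marks), function(mk) {
    lapply(setNames(c("c1", "c2"), c("c1", "c2")), function(cond) {
      list(ip = frag_lib(mk, cond, "IP"),
           input = frag_lib(mk, cond, "INPUT"))
    })
  })

  # --- peaks over regions enriched (fold > 1) in each condition, jittered
  peaks <- lapply(setNames(marks, marks), function(mk) {
    tr <- truth_regions[truth_regions$mark == mk, , drop = FALSE]
    lapply(setNames(c("c1", "c2"), c("c1", "c2")), function(cond) {
      fold <- if (cond == "c1") tr$fold_c1 else tr$fold_c2
      sel <- tr[fold > 1, , drop = FALSE]
      if (!nrow(sel)) {
        return(GenomicRanges::GRanges(name = character(0), score = numeric(0)))
      }
      j1 <- round(runif(nrow(sel), -cfg$peak_jitter, cfg$peak_jitter))
      j2 <- round(runif(nrow(sel), -cfg$peak_jitter, cfg$peak_jitter))
      s0 <- pmax(sel$start0 + j1, 0)
      e0 <- pmax(sel$end0 + j2, s0 + 50)
      GenomicRanges::GRanges(sel$chrom, IRanges::IRanges(s0 + 1, e0),
                             name = sprintf("%s_%s", sel$region_id, cond),
                             score = fold[fold > 1])
    })
  })

  # --- RNA-seq counts (negative binomial), DE table, normalized expression
  n_s1 <- cfg$n_samples_c1; n_s2 <- cfg$n_samples_c2
  base_mu <- 2^runif(n, 4, 13)
  mu <- cbind(matrix(base_mu, n, n_s1),
              matrix(base_mu * 2^log2fc, n, n_s2))
  size <- 1 / cfg$nb_dispersion
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                   nrow = n,
                   dimnames = list(genes$gene_id,
                                   c(sprintf("c1_s%d", seq_len(n_s1)),
                                     sprintf("c2_s%d", seq_len(n_s2)))))
  norm <- normalize_expression_standin(counts)
  de <- data.frame(gene_id = genes$gene_id, log2fc = log2fc, padj = padj,
                   stringsAsFactors = FALSE)
  truth_genes <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                            strand = genes$strand, tss0 = tss0,
                            true_direction = dir_vec, true_log2fc = log2fc,
                            coupled_k4_gain = coupled,
                            stringsAsFactors = FALSE)

  gtf_lines <- gene_models_gtf(genes)
  gm <- read_gtf_lines(gtf_lines)

  out <- list(gene_models = gm, peaks = peaks, fragments = fragments,
              counts = counts, de = de, expr = norm$values,
              truth_genes = truth_genes, truth_regions = truth_regions,
              config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    files <- c(genes_gtf = p("genes.gtf"))
    writeLines(gtf_lines, p("genes.gtf"))
    for (mk in marks) {
      for (cond in c("c1", "c2")) {
        f1 <- p(sprintf("peaks_%s_%s.bed", mk, cond))
        write_bed(peaks[[mk]][[cond]], f1)
        f2 <- p(sprintf("ip_%s_%s.bed", mk, cond))
        write_bed(fragments[[mk]][[cond]]$ip$fragments, f2)
        f3 <- p(sprintf("input_%s_%s.bed", mk, cond))
        write_bed(fragments[[mk]][[cond]]$input$fragments, f3)
        files[sprintf("peaks_%s_%s", mk, cond)] <- f1
        files[sprintf("ip_%s_%s", mk, cond)] <- f2
        files[sprintf("input_%s_%s", mk, cond)] <- f3
      }
    }
    write_tsv_file <- function(df, name) {
      write.table(df, p(name), sep = "\t", quote = FALSE, row.names = FALSE)
      files[name] <<- p(name)
    }
    write_tsv_file(data.frame(gene_id = rownames(counts), counts,
                              check.names = FALSE), "counts.tsv")
    write_tsv_file(de, "de.tsv")
    write_tsv_file(data.frame(gene_id = rownames(norm$values),
                              round(norm$values, 6), check.names = FALSE),
                   "expr.tsv")
    write_tsv_file(truth_genes, "truth_genes.tsv")
    write_tsv_file(truth_regions, "truth_regions.tsv")
    out$files <- files
  }
  out
}

# parse GTF text already in memory (avoids a write/read round trip)
read_gtf_lines <- function(lines) {
  tf <- tempfile(fileext = ".gtf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  read_gene_models(tf)
}

#' Score called differential regions against simulation truth
#'
#' Matches every truth region (by >= 1 bp overlap) with the called merged
#' regions of the same mark and scores recovery: sensitivity is the
#' fraction of truly increased (resp. decreased) regions overlapped by a
#' called region of that class; the false-increase rate is the fraction of
#' truly flat regions overlapped by a called increased region.
#'
#' @param called Region-signal data frame from
#'   [call_differential_regions()].
#' @param truth The `truth_regions` rows for the same mark.
#' @return A list with `n_true_increased`, `n_true_decreased`, `n_flat`,
#'   `sensitivity_increased`, `sensitivity_decreased`,
#'   `false_increase_rate`.
#' @export
score_region_calls <- function(called, truth) {
  tr_gr <- GenomicRanges::GRanges(truth$chrom,
                                  IRanges::IRanges(truth$start0 + 1, truth$end0))
  call_class_over <- function(cls) {
    sub <- called[called$change_class == cls, , drop = FALSE]
    if (!nrow(sub)) return(logical(nrow(truth)))
    GenomicRanges::countOverlaps(
      tr_gr, as_region_granges(sub), ignore.strand = TRUE) > 0
  }
  hit_inc <- call_class_over("increased")
  hit_dec <- call_class_over("decreased")
  is_inc <- truth$true_class == "increased"
  is_dec <- truth$true_class == "decreased"
  is_flat <- truth$true_class == "flat"
  list(n_true_increased = sum(is_inc),
       n_true_decreased = sum(is_dec),
       n_flat = sum(is_flat),
       sensitivity_increased = if (any(is_inc)) mean(hit_inc[is_inc]) else NA_real_,
       sensitivity_decreased = if (any(is_dec)) mean(hit_dec[is_dec]) else NA_real_,
       false_increase_rate = if (any(is_flat)) mean(hit_inc[is_flat]) else NA_real_)
}
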