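# End-to-end orchestration: simulate -> differential regions (both marks)
# -> annotation and TSS profiles -> expression integration, with a written
# report and a reproducibility manifest.

#' Run the full pipeline on a simulated dataset
#'
#' Executes every stage on data from [simulate_dataset()] and writes a
#' report directory: per-mark differential-region tables and class counts,
#' feature-category distributions (overall and per change class), TSS
#' metaprofiles stratified by expression, the 2 x 4 gene-group table with
#' row percentages, the paired expression-shift test on up-regulated genes
#' with a proximal H3K4me3-increased region, and a `manifest.json` with the
#' config, package version, per-stage row counts and md5 checksums of every
#' written file. Runs with the same config are byte-identical. A stage
#' failure removes the partial output directory and reports the stage name.
#'
#' @param config A [sim_config()]; its `seed` drives all randomness.
#' @param out_dir Report directory (created; must not be an existing
#'   non-empty directory unless `overwrite = TRUE`).
#' @param max_gap,fold_threshold,pseudocount Differential-region parameters
#'   (defaults 1000 bp, 2-fold, 1).
#' @param promoter_halfwidth,downstream_len Annotation windows in bp.
#' @param tss_window,tss_bin TSS profile half-width and bin size in bp.
#' @param expr_threshold Expression split for profile strata (default 10).
#' @param alpha DE adjusted-p threshold (default 0.01).
#' @param proximal_dist Proximal-promoter distance in bp (default 1000).
#' @param overwrite Remove an existing `out_dir` first (default `FALSE`).
#' @param quiet Suppress per-stage log lines (default `FALSE`).
#' @return Invisibly, a list with the in-memory results of every stage and
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir,
                         max_gap = 1000, fold_threshold = 2, pseudocount = 1,
                         promoter_halfwidth = 3000, downstream_len = 3000,
                         tss_window = 5000, tss_bin = 100,
                         expr_threshold = 10, alpha = 0.01,
                         proximal_dist = 1000,
                         overwrite = FALSE, quiet = FALSE) {
  if (dir.exists(out_dir)) {
    if (overwrite) {
      unlink(out_dir, recursive = TRUE)
    } else if (length(list.files(out_dir))) {
      stopf("out_dir exists and is not empty: %s", out_dir)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- TRUE
  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage_counts <- list()
  run_stage <- function(stage, code) {
    tryCatch(force(code), error = function(e) {
      unlink(out_dir, recursive = TRUE)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  p <- function(...) file.path(out_dir, ...)
  marks <- c("H3K4me3", "H3K27ac")

  sim <- run_stage("simulate", simulate_dataset(config, out_dir = p("sim")))
  stage_counts$simulate <- list(genes = length(sim$gene_models$genes),
                                truth_regions = nrow(sim$truth_regions))
  log_line("simulate", "%d genes, %d truth regions",
           length(sim$gene_models$genes), nrow(sim$truth_regions))

  regions <- run_stage("diff_regions", {
    lapply(setNames(marks, marks), function(mk) {
      fr <- sim$fragments[[mk]]
      df <- call_differential_regions(
        sim$peaks[[mk]]$c1, sim$peaks[[mk]]$c2,
        fr$c1$ip, fr$c1$input, fr$c2$ip, fr$c2$input,
        mark = mk, max_gap = max_gap, fold_threshold = fold_threshold,
        pseudocount = pseudocount)
      write_regions_tsv(df, p(sprintf("regions_%s.tsv", mk)))
      df
    })
  })
  rc <- diff_region_counts(regions)
  write.table(rc, p("diff_region_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_counts$diff_regions <- setNames(as.list(rc$total), rc$mark)
  for (i in seq_len(nrow(rc))) {
    log_line("diff_regions", "%s: %d increased, %d decreased, %d unchanged",
             rc$mark[i], rc$increased[i], rc$decreased[i], rc$unchanged[i])
  }

  annot <- run_stage("annotate", {
    res <- list()
    for (mk in marks) {
      ann <- annotate_regions(regions[[mk]], sim$gene_models,
                              promoter_halfwidth = promoter_halfwidth,
                              downstream_len = downstream_len)
      res[[mk]] <- ann
      write.table(ann, p(sprintf("annotated_%s.tsv", mk)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    res
  })
  dist_rows <- run_stage("annotate", {
    rows <- list()
    for (mk in marks) {
      ann <- annot[[mk]]
      subsets <- list(all = ann,
                      increased = ann[ann$change_class == "increased", ],
                      decreased = ann[ann$change_class == "decreased", ])
      for (nm in names(subsets)) {
        if (!nrow(subsets[[nm]])) next
        d <- category_distribution(subsets[[nm]])
        d$percent <- round_half_up(d$percent, 1)
        rows[[paste(mk, nm)]] <- cbind(mark = mk, subset = nm, d)
      }
    }
    do.call(rbind, rows)
  })
  write.table(dist_rows, p("category_distribution.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stage_counts$annotate <- setNames(lapply(annot, nrow), marks)
  log_line("annotate", "category tables for %d marks", length(marks))

  expr_vec <- rowMeans(sim$expr)
  profiles <- run_stage("tss_profile", {
    rows <- list()
    for (mk in marks) {
      for (cond in c("c1", "c2")) {
        pr <- tss_profile(sim$fragments[[mk]][[cond]]$ip, sim$gene_models,
                          expr_vec, expr_threshold = expr_threshold,
                          window = tss_window, bin = tss_bin)
        tb <- tss_profile_table(pr)
        rows[[paste(mk, cond)]] <- cbind(mark = mk, condition = cond, tb)
      }
    }
    do.call(rbind, rows)
  })
  write.table(profiles, p("tss_profiles.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_counts$tss_profile <- nrow(profiles)
  log_line("tss_profile", "%d profile rows", nrow(profiles))

  integ <- run_stage("integrate", {
    de_split <- filter_de(sim$de, alpha = alpha)
    flags <- assign_regions_to_genes(regions, sim$gene_models,
                                     proximal_dist = proximal_dist)
    grp <- group_genes(de_split, flags, marks = marks)
    grp_prox <- group_genes(de_split, flags, marks = marks, proximal = TRUE)
    focus <- de_split$up[de_split$up %in%
                           flags$gene_id[flags$H3K4me3_increased_proximal]]
    shift <- if (length(focus) >= 2) {
      cond <- ifelse(grepl("^c1_", colnames(sim$expr)), "c1", "c2")
      expression_shift_test(focus, sim$expr, cond)
    } else {
      NULL
    }
    list(de_split = de_split, flags = flags, groups = grp,
         groups_proximal = grp_prox, focus_genes = focus, shift = shift)
  })
  counts_df <- data.frame(direction = rownames(integ$groups$counts),
                          integ$groups$counts, total = rowSums(integ$groups$counts),
                          check.names = FALSE)
  pct <- group_percentages(integ$groups$counts)
  write.table(counts_df, p("group_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(direction = rownames(pct), pct, check.names = FALSE),
              p("group_percentages.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(integ$groups$assignments, p("gene_groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  assoc <- c(sprintf("genes tested: %d (up-regulated with proximal H3K4me3-increased region)",
                     length(integ$focus_genes)),
             if (!is.null(integ$shift)) c(
               sprintf("test: paired two-sided %s signed-rank", integ$shift$method),
               sprintf("statistic: %g", integ$shift$statistic),
               sprintf("p_value: %g", integ$shift$p_value),
               sprintf("mean_expression_c1: %.4f", integ$shift$mean_c1),
               sprintf("mean_expression_c2: %.4f", integ$shift$mean_c2))
             else "test: skipped (fewer than 2 focus genes)")
  writeLines(assoc, p("association.txt"))
  stage_counts$integrate <- list(up = length(integ$de_split$up),
                                 down = length(integ$de_split$down),
                                 focus = length(integ$focus_genes))
  log_line("integrate", "%d up / %d down DE genes; %d focus genes",
           length(integ$de_split$up), length(integ$de_split$down),
           length(integ$focus_genes))

  files <- sort(list.files(out_dir, recursive = TRUE))
  checks <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(package = "histofold",
                   version = as.character(utils::packageVersion("histofold")),
                   seed = config$seed,
                   config = unclass(config),
                   parameters = list(max_gap = max_gap,
                                     fold_threshold = fold_threshold,
                                     pseudocount = pseudocount,
                                     promoter_halfwidth = promoter_halfwidth,
                                     downstream_len = downstream_len,
                                     tss_window = tss_window,
                                     tss_bin = tss_bin,
                                     expr_threshold = expr_threshold,
                                     alpha = alpha,
                                     proximal_dist = proximal_dist),
                   stage_counts = stage_counts,
                   checksums = as.list(setNames(unname(checks), files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_line("report", "written to %s", out_dir)

  invisible(list(sim = sim, regions = regions, region_counts = rc,
                 annotation = annot, distributions = dist_rows,
                 profiles = profiles, integration = integ,
                 manifest = manifest))
}
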