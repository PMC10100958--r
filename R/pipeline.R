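# End-to-end pipeline over a cohort directory, and the CLI entry point.

fmt_num <- function(x) {
  # fixed-width scientific keeps output byte-stable across runs
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

write_result_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  write_tsv(df, path)
}

#' Run the full analysis pipeline over a cohort directory
#'
#' Reads the feature tables, metadata, immunity panel and per-sample VCFs
#' written by [write_cohort()] (or assembled in the same formats from real
#' data), and runs: per-layer Shannon diversity, Bray-Curtis PERMANOVA
#' (group effect at each timepoint), within-group convergence tests,
#' metabolite QC + CLR, per-group paired differential testing with
#' time-effect subtraction and the direct-influence summary, the
#' delta-correlation indirect-influence screen, and the SNV attribution
#' procedure.  All results are written as TSVs under `out_dir`; identical
#' inputs and config produce byte-identical output trees.
#'
#' @param input_dir cohort directory.
#' @param out_dir output directory (created).
#' @param config nested config list from [read_config()] /
#'   [default_config()].
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(input_dir, out_dir, config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  co <- read_cohort(input_dir, cfg$vcf$min_quality, cfg$vcf$min_depth)
  md <- co$metadata
  results <- list()

  # ---- metabolite QC + CLR -------------------------------------------------
  qc <- NULL
  tables <- co$tables
  clr_met <- NULL
  if (!is.null(tables$metabolite)) {
    qc <- metabolite_qc(tables$metabolite, cfg$qc$min_intensity,
                        cfg$qc$min_prevalence, cfg$qc$max_rsd,
                        cfg$qc$rsd_scope)
    tables$metabolite <- qc$table
    clr_met <- clr_transform(qc$table, cfg$clr$pseudocount_factor)
    write_result_tsv(data.frame(
      n_features_in = qc$report$n_features_in,
      n_removed_intensity = qc$report$n_removed_intensity,
      n_removed_prevalence = qc$report$n_removed_prevalence,
      n_removed_rsd = qc$report$n_removed_rsd,
      n_features_out = qc$report$n_features_out),
      file.path(out_dir, "metabolite_qc_report.tsv"))
  }
  results$qc <- qc

  # ---- diversity and convergence ------------------------------------------
  shannon_rows <- NULL
  permanova_rows <- NULL
  ranksum_rows <- NULL
  signedrank_rows <- NULL
  for (layer in names(tables)) {
    tb <- tables[[layer]]
    X <- tb$values
    H <- apply(X, 1, shannon)
    shannon_rows <- rbind(shannon_rows, data.frame(
      layer = layer, sample_id = rownames(X), shannon = unname(H),
      stringsAsFactors = FALSE))
    dms <- lapply(TIMEPOINTS, function(tp) distance_matrix(tb, timepoint = tp))
    names(dms) <- TIMEPOINTS
    for (tp in TIMEPOINTS) {
      lab <- dms[[tp]]$samples$group
      pr <- permanova(dms[[tp]], lab, cfg$diversity$n_permutations,
                      seed = cfg$diversity$seed)
      permanova_rows <- rbind(permanova_rows, data.frame(
        layer = layer, timepoint = tp, pseudo_F = pr$pseudo_F,
        p_value = pr$p_value, n_permutations = pr$n_permutations,
        stringsAsFactors = FALSE))
    }
    cv <- convergence_tests(dms$baseline, dms$endline)
    ranksum_rows <- rbind(ranksum_rows,
                          cbind(layer = layer, cv$rank_sum))
    signedrank_rows <- rbind(signedrank_rows,
                             cbind(layer = layer, cv$signed_rank))
  }
  write_result_tsv(shannon_rows, file.path(out_dir, "shannon.tsv"))
  write_result_tsv(permanova_rows, file.path(out_dir, "permanova.tsv"))
  write_result_tsv(ranksum_rows, file.path(out_dir, "convergence_rank_sum.tsv"))
  write_result_tsv(signedrank_rows,
                   file.path(out_dir, "convergence_signed_rank.tsv"))
  results$permanova <- permanova_rows
  results$convergence <- list(rank_sum = ranksum_rows,
                              signed_rank = signedrank_rows)

  # immunity-change PERMANOVA (group effect on per-subject deltas)
  imm_deltas <- lapply(stats::setNames(GROUPS, GROUPS),
                       function(g) subject_deltas(co$immunity, g))
  dd <- delta_distance(imm_deltas, cfg$diversity$standardize_deltas)
  pr <- permanova(dd$d, dd$groups, cfg$diversity$n_permutations,
                  seed = cfg$diversity$seed)
  write_result_tsv(data.frame(pseudo_F = pr$pseudo_F, p_value = pr$p_value,
                              n_permutations = pr$n_permutations),
                   file.path(out_dir, "immunity_delta_permanova.tsv"))
  results$immunity_delta_permanova <- pr

  # ---- paired differential + direct influence -----------------------------
  direct_rows <- NULL
  for (layer in names(tables)) {
    raw <- tables[[layer]]
    test_tb <- if (layer == "metabolite") clr_met else raw
    res <- lapply(stats::setNames(GROUPS, GROUPS), function(g) {
      paired_change_test(test_tb, g, cfg$differential$alpha,
                         cfg$differential$min_pairs,
                         raw = if (layer == "metabolite") raw else NULL)
    })
    diff <- time_effect_subtraction(res$placebo, res$probiotic,
                                    cfg$differential$alpha,
                                    cfg$differential$strict_probiotic_only,
                                    cfg$differential$fdr)
    diff$median_change_fraction_probiotic <-
      res$probiotic$median_change_fraction
    write_result_tsv(diff, file.path(out_dir,
                                     paste0("differential_", layer, ".tsv")))
    ds <- direct_influence_summary(diff, raw)
    direct_rows <- rbind(direct_rows, data.frame(
      layer = layer, n_differential = ds$n_differential, n_total = ds$n_total,
      count_ratio = ds$count_ratio, proportion = ds$proportion,
      stringsAsFactors = FALSE))
    results$differential[[layer]] <- diff
  }
  # immunity indicators get the same paired procedure (no proportion summary)
  imm_res <- lapply(stats::setNames(GROUPS, GROUPS), function(g) {
    paired_change_test(co$immunity, g, cfg$differential$alpha,
                       cfg$differential$min_pairs)
  })
  imm_diff <- time_effect_subtraction(imm_res$placebo, imm_res$probiotic,
                                      cfg$differential$alpha,
                                      cfg$differential$strict_probiotic_only,
                                      cfg$differential$fdr)
  imm_diff$median_change_fraction_probiotic <-
    imm_res$probiotic$median_change_fraction
  write_result_tsv(imm_diff, file.path(out_dir, "differential_immunity.tsv"))
  write_result_tsv(direct_rows, file.path(out_dir, "direct_influence.tsv"))
  results$direct <- direct_rows
  results$differential$immunity <- imm_diff

  # ---- indirect influence --------------------------------------------------
  indirect_rows <- NULL
  all_edges <- NULL
  for (layer in names(tables)) {
    tb <- if (layer == "metabolite") clr_met else tables[[layer]]
    un <- remove_shared_edges(
      correlate_group(subject_deltas(tb, "probiotic"),
                      imm_deltas$probiotic, cfg$indirect$alpha,
                      cfg$indirect$fdr),
      correlate_group(subject_deltas(tb, "placebo"),
                      imm_deltas$placebo, cfg$indirect$alpha,
                      cfg$indirect$fdr))
    su <- indirect_influence_summary(un, tables[[layer]],
                                     cfg$indirect$union_proportion)
    indirect_rows <- rbind(indirect_rows, data.frame(
      layer = layer, n_implicated = su$n_implicated, n_total = su$n_total,
      count_ratio = su$count_ratio, proportion = su$proportion,
      stringsAsFactors = FALSE))
    lab <- function(df, status) {
      if (nrow(df)) cbind(layer = layer, df, status = status) else NULL
    }
    all_edges <- rbind(all_edges,
                       lab(un$unique_probiotic, "unique"),
                       lab(un$unique_placebo, "unique"),
                       lab(un$shared, "shared"))
    results$indirect[[layer]] <- list(edges = un, summary = su)
  }
  write_result_tsv(indirect_rows, file.path(out_dir, "indirect_influence.tsv"))
  if (!is.null(all_edges)) {
    write_result_tsv(all_edges, file.path(out_dir, "indirect_edges.tsv"))
  }
  results$indirect_summary <- indirect_rows

  # ---- SNV attribution -----------------------------------------------------
  if (length(co$snv)) {
    changes <- cohort_temporal_changes(co$snv, md)
    n_paired <- vapply(stats::setNames(GROUPS, GROUPS),
                       function(g) length(paired_subjects(md, g)), 1L)
    cands <- lapply(stats::setNames(GROUPS, GROUPS), function(g) {
      group_candidate_snvs(changes, g,
                           if (cfg$snv$pooled_prevalence) sum(n_paired)
                           else n_paired[[g]],
                           cfg$snv$prevalence, cfg$snv$direction_scope)
    })
    attr_res <- venn_subtract(cands$probiotic, cands$placebo)
    uniq_df <- rbind(
      cbind(snv_key_df(attr_res$unique_probiotic),
            group = rep("probiotic", length(attr_res$unique_probiotic))),
      cbind(snv_key_df(attr_res$unique_placebo),
            group = rep("placebo", length(attr_res$unique_placebo))),
      cbind(snv_key_df(attr_res$shared),
            group = rep("shared", length(attr_res$shared))))
    write_result_tsv(uniq_df, file.path(out_dir, "snv_attribution.tsv"))
    if (!is.null(co$sgb_species)) {
      sp <- species_categorize(attr_res, co$sgb_species, co$tables$bacteria)
      write_result_tsv(sp, file.path(out_dir, "snv_species.tsv"))
      results$snv_species <- sp
    }
    si <- correlate_snv_immunity(attr_res, changes, imm_deltas,
                                 co$immunity$categories, cfg$snv$alpha)
    write_result_tsv(si$edges, file.path(out_dir, "snv_immunity_edges.tsv"))
    write_result_tsv(si$summary,
                     file.path(out_dir, "snv_immunity_summary.tsv"))
    results$snv <- list(attribution = attr_res, immunity = si)
  }
  invisible(results)
}

# ---- CLI -------------------------------------------------------------------

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`--out DIR --seed N [--subjects N]` — write a synthetic
#'     cohort.}
#'   \item{run}{`--in DIR --out DIR [--config FILE] [--alpha X]
#'     [--min-quality Q] [--min-depth D] [--prevalence P]
#'     [--permutations N] [--seed N] [--verbose]` — run the pipeline; flags
#'     override the config file, which overrides the defaults.}
#'   \item{all}{`--out DIR --seed N` — simulate into `DIR/cohort` and run
#'     into `DIR/results`.}
#' }
#'
#' @param args character vector of CLI arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args) {
  if (!length(args)) {
    cat("usage: deltaomics <simulate|run|all> [--flags]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  flags <- .parse_flags(args[-1])
  if (isTRUE(flags$verbose) || identical(flags$verbose, "TRUE")) {
    old <- options(deltaomics.verbose = TRUE)
    on.exit(options(old), add = TRUE)
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  if (cmd == "simulate" || cmd == "all") {
    out <- flags$out
    if (is.null(out)) stop("simulate needs --out")
    cdir <- if (cmd == "all") file.path(out, "cohort") else out
    cfg <- cohort_config(
      n_subjects_per_group = as.integer(num(flags$subjects, 45)),
      seed = as.integer(num(flags$seed, 1)))
    write_cohort(generate_cohort(cfg), cdir)
    if (cmd == "simulate") return(invisible(0L))
  }
  if (cmd == "run" || cmd == "all") {
    input <- if (cmd == "all") file.path(flags$out, "cohort") else flags[["in"]]
    out <- if (cmd == "all") file.path(flags$out, "results") else flags$out
    if (is.null(input) || is.null(out)) stop("run needs --in and --out")
    cfg <- read_config(flags$config)
    if (!is.null(flags$alpha)) {
      a <- as.numeric(flags$alpha)
      cfg$differential$alpha <- a
      cfg$indirect$alpha <- a
      cfg$snv$alpha <- a
    }
    cfg$vcf$min_quality <- num(flags[["min-quality"]], cfg$vcf$min_quality)
    cfg$vcf$min_depth <- num(flags[["min-depth"]], cfg$vcf$min_depth)
    cfg$snv$prevalence <- num(flags$prevalence, cfg$snv$prevalence)
    cfg$diversity$n_permutations <- as.integer(
      num(flags$permutations, cfg$diversity$n_permutations))
    cfg$diversity$seed <- as.integer(num(flags$seed, cfg$diversity$seed))
    run_pipeline(input, out, cfg)
    return(invisible(0L))
  }
  if (!cmd %in% c("simulate", "run", "all")) stop("unknown subcommand: ", cmd)
  invisible(0L)
}
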