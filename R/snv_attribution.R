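# SNV treatment attribution: within-host temporal changes, cohort prevalence
# filtering, placebo subtraction (Venn), per-species categorisation and
# SNV-immunity association.

#' Within-host temporal SNV changes
#'
#' Compares the baseline and endline call sets of one host: `gained` = calls
#' present only at endline, `lost` = calls present only at baseline.
#'
#' @param baseline,endline [snv_callset()] objects of the same subject at
#'   `baseline` and `endline`.
#' @return data.frame: `subject_id`, `key`, `direction` (`gained`/`lost`).
#' @export
host_temporal_changes <- function(baseline, endline) {
  if (!identical(baseline$sample$subject_id, endline$sample$subject_id)) {
    stop("call sets come from different subjects")
  }
  if (baseline$sample$timepoint != "baseline" ||
      endline$sample$timepoint != "endline") {
    stop("expected one baseline and one endline call set")
  }
  gained <- setdiff(endline$calls, baseline$calls)
  lost <- setdiff(baseline$calls, endline$calls)
  key <- c(gained, lost)
  out <- data.frame(
    subject_id = rep(baseline$sample$subject_id, length(key)),
    key = key,
    direction = rep(c("gained", "lost"), c(length(gained), length(lost))),
    stringsAsFactors = FALSE)
  out[order(out$key), , drop = FALSE]
}

#' Collect temporal changes for every paired subject
#'
#' @param callsets named list of [snv_callset()] (all samples).
#' @param metadata sample metadata.
#' @return data.frame of [host_temporal_changes()] rows plus `group`.
#' @export
cohort_temporal_changes <- function(callsets, metadata) {
  md <- validate_metadata(metadata)
  subs <- paired_subjects(md)
  rows <- lapply(subs, function(s) {
    ids <- md[md$subject_id == s, , drop = FALSE]
    b <- callsets[[ids$sample_id[ids$timepoint == "baseline"]]]
    e <- callsets[[ids$sample_id[ids$timepoint == "endline"]]]
    if (is.null(b) || is.null(e)) stop("missing call set for subject ", s)
    ch <- host_temporal_changes(b, e)
    if (nrow(ch)) ch$group <- ids$group[1]
    ch
  })
  out <- do.call(rbind, rows[vapply(rows, nrow, 1L) > 0])
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), key = character(),
                      direction = character(), group = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Group-level candidate SNVs by prevalence filtering
#'
#' Keeps SNV keys whose temporal change is observed in at least
#' `prevalence_threshold` (inclusive) of the group's paired subjects.  With
#' `direction_scope = "either"` (default) a gain or a loss both count; with
#' `"gained"` only gains do.
#'
#' @param changes data.frame from [cohort_temporal_changes()] (or the
#'   per-subject rows of one group).
#' @param group group to filter for.
#' @param n_subjects number of paired subjects in the group (the prevalence
#'   denominator).
#' @param prevalence_threshold minimum fraction of subjects (default 0.30).
#' @param direction_scope `"either"` or `"gained"`.
#' @return list (class `group_snv_set`): `group`, `snvs` (data.frame `key`,
#'   `n_subjects`, `fraction`), `n_group_subjects`.
#' @export
group_candidate_snvs <- function(changes, group, n_subjects,
                                 prevalence_threshold = 0.30,
                                 direction_scope = c("either", "gained")) {
  direction_scope <- match.arg(direction_scope)
  group <- match.arg(group, GROUPS)
  if (n_subjects < 1) stop("empty group")
  ch <- changes
  if ("group" %in% names(ch)) ch <- ch[ch$group == group, , drop = FALSE]
  if (direction_scope == "gained") {
    ch <- ch[ch$direction == "gained", , drop = FALSE]
  }
  counts <- if (nrow(ch)) {
    tapply(ch$subject_id, ch$key, function(s) length(unique(s)))
  } else {
    stats::setNames(integer(0), character(0))
  }
  frac <- as.numeric(counts) / n_subjects
  keep <- which(frac >= prevalence_threshold - 1e-12)
  snvs <- data.frame(key = as.character(names(counts)[keep]),
                     n_subjects = as.integer(counts[keep]),
                     fraction = frac[keep], stringsAsFactors = FALSE)
  snvs <- snvs[order(snvs$key), , drop = FALSE]
  rownames(snvs) <- NULL
  do_log("group_candidate_snvs(%s): %d keys in, %d kept at prevalence >= %g",
         group, length(counts), nrow(snvs), prevalence_threshold)
  structure(list(group = group, snvs = snvs, n_group_subjects = n_subjects),
            class = "group_snv_set")
}

#' Placebo subtraction of candidate SNVs (Venn)
#'
#' The intersection of the two groups' candidate sets is attributed to time
#' development and removed; the set differences are the treatment-attributed
#' unique SNVs.
#'
#' @param candidates_probiotic,candidates_placebo [group_candidate_snvs()]
#'   results.
#' @return list (class `attribution_result`): `unique_probiotic`,
#'   `unique_placebo`, `shared` (character key vectors) and `prevalence`
#'   (both groups' prevalence tables).
#' @export
venn_subtract <- function(candidates_probiotic, candidates_placebo) {
  a <- candidates_probiotic$snvs$key
  b <- candidates_placebo$snvs$key
  shared <- intersect(a, b)
  structure(list(unique_probiotic = sort(setdiff(a, b)),
                 unique_placebo = sort(setdiff(b, a)),
                 shared = sort(shared),
                 prevalence = list(probiotic = candidates_probiotic$snvs,
                                   placebo = candidates_placebo$snvs),
                 n_group_subjects = list(
                   probiotic = candidates_probiotic$n_group_subjects,
                   placebo = candidates_placebo$n_group_subjects)),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> unique: probiotic %d, placebo %d; shared %d\n",
              length(x$unique_probiotic), length(x$unique_placebo),
              length(x$shared)))
  invisible(x)
}

#' Per-species categorisation of unique SNVs
#'
#' Groups each arm's unique SNVs by the species of their source SGB and
#' builds the species table: counts per arm, their sum, dense ranks
#' (descending count, ties share a rank; ranks beyond `top_k` in an arm are
#' rendered as NA, mirroring a top-k table layout), and the mean relative
#' abundance of the species' SGBs per arm.
#'
#' @param result an [venn_subtract()] result.
#' @param sgb_species_map named character vector sgb_id -> species.
#' @param abundances bacteria [feature_table()] whose feature ids are SGB
#'   ids (mean is taken over each arm's samples).
#' @param top_k rank cut-off for the rendered ranks (default 10).
#' @return data.frame: `species`, `n_probiotic`, `n_placebo`, `n_sum`,
#'   `rank_probiotic`, `rank_placebo`, `rank_sum`, `mean_abund_probiotic`,
#'   `mean_abund_placebo`, ordered by descending `n_sum`.
#' @export
species_categorize <- function(result, sgb_species_map, abundances = NULL,
                               top_k = 10) {
  keys <- c(result$unique_probiotic, result$unique_placebo)
  grp <- rep(c("probiotic", "placebo"),
             c(length(result$unique_probiotic), length(result$unique_placebo)))
  df <- snv_key_df(keys)
  unmapped <- setdiff(unique(df$sgb_id), names(sgb_species_map))
  if (length(unmapped)) {
    stop("unmapped sgb_id(s): ", paste(unmapped, collapse = ", "))
  }
  species <- unname(sgb_species_map[df$sgb_id])
  all_sp <- sort(unique(species))
  count_of <- function(g) {
    tab <- table(factor(species[grp == g], levels = all_sp))
    as.integer(tab)
  }
  out <- data.frame(species = all_sp,
                    n_probiotic = count_of("probiotic"),
                    n_placebo = count_of("placebo"),
                    stringsAsFactors = FALSE)
  out$n_sum <- out$n_probiotic + out$n_placebo
  dense_rank <- function(n) {
    r <- match(n, sort(unique(n[n > 0]), decreasing = TRUE))
    r[n == 0] <- NA_integer_
    r
  }
  out$rank_probiotic <- dense_rank(out$n_probiotic)
  out$rank_placebo <- dense_rank(out$n_placebo)
  out$rank_sum <- dense_rank(out$n_sum)
  out$rank_probiotic[!is.na(out$rank_probiotic) &
                       out$rank_probiotic > top_k] <- NA_integer_
  out$rank_placebo[!is.na(out$rank_placebo) &
                     out$rank_placebo > top_k] <- NA_integer_
  if (!is.null(abundances)) {
    md <- abundances$samples
    for (g in GROUPS) {
      X <- abundances$values[md$sample_id[md$group == g], , drop = FALSE]
      mab <- colMeans(X)
      sp_ab <- vapply(all_sp, function(s) {
        sgb <- names(sgb_species_map)[sgb_species_map == s]
        sum(mab[intersect(sgb, colnames(X))])
      }, 0)
      out[[paste0("mean_abund_", g)]] <- unname(sp_ab)
    }
  }
  out <- out[order(-out$n_sum, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate group-unique SNVs with immunity-indicator changes
#'
#' Within each arm, every group-unique SNV is encoded per paired subject as
#' 1 if the subject shows the temporal change and 0 otherwise; the encoding
#' is Spearman-correlated against each indicator's per-subject delta.
#' Edges with `p < alpha` are kept.  Constant encodings (no or all carriers)
#' are skipped and logged.
#'
#' @param result an [venn_subtract()] result.
#' @param changes [cohort_temporal_changes()] data.frame.
#' @param immunity_deltas named list of [subject_deltas()] of the immunity
#'   panel, one per group.
#' @param categories named character vector indicator -> category.
#' @param alpha p-value threshold (default 0.05).
#' @return list with `edges` (data.frame `group`, `key`, `indicator`, `rho`,
#'   `p_value`, `sign`) and `summary` (per group x category: number of
#'   associated SNVs, number of associated indicators, most-associated
#'   indicator).
#' @export
correlate_snv_immunity <- function(result, changes, immunity_deltas,
                                   categories, alpha = 0.05) {
  edges <- NULL
  n_skipped <- 0L
  for (g in GROUPS) {
    uniq <- result[[paste0("unique_", g)]]
    if (!length(uniq)) next
    dimm <- immunity_deltas[[g]]
    subs <- dimm$subjects
    ch <- changes[changes$group == g & changes$key %in% uniq, , drop = FALSE]
    enc <- matrix(0, length(subs), length(uniq),
                  dimnames = list(subs, uniq))
    if (nrow(ch)) {
      ch <- ch[ch$subject_id %in% subs, , drop = FALSE]
      enc[cbind(match(ch$subject_id, subs), match(ch$key, uniq))] <- 1
    }
    const <- apply(enc, 2, function(v) length(unique(v)) == 1L)
    n_skipped <- n_skipped + sum(const)
    if (all(const)) next
    enc <- enc[, !const, drop = FALSE]
    gr <- spearman_grid(enc, dimm$values)
    keep <- which(!is.na(gr$p) & gr$p < alpha, arr.ind = TRUE)
    if (nrow(keep)) {
      edges <- rbind(edges, data.frame(
        group = g,
        key = colnames(enc)[keep[, 1]],
        indicator = dimm$columns[keep[, 2]],
        rho = gr$rho[keep], p_value = gr$p[keep],
        sign = ifelse(gr$rho[keep] > 0, "+", "-"),
        stringsAsFactors = FALSE))
    }
  }
  if (n_skipped) do_log("correlate_snv_immunity: %d constant encodings skipped",
                        n_skipped)
  if (is.null(edges)) {
    edges <- data.frame(group = character(), key = character(),
                        indicator = character(), rho = numeric(),
                        p_value = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$group, edges$key, edges$indicator), , drop = FALSE]
  rownames(edges) <- NULL
  summ <- do.call(rbind, lapply(GROUPS, function(g) {
    do.call(rbind, lapply(unique(unname(categories)), function(cc) {
      inds <- names(categories)[categories == cc]
      e <- edges[edges$group == g & edges$indicator %in% inds, , drop = FALSE]
      top <- if (nrow(e)) {
        tt <- sort(table(e$indicator), decreasing = TRUE)
        names(tt)[1]
      } else NA_character_
      data.frame(group = g, category = cc,
                 n_snvs = length(unique(e$key)),
                 n_indicators = length(unique(e$indicator)),
                 top_indicator = top, stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  list(edges = edges, summary = summ)
}
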