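# Metabolomics QC + CLR, per-group paired change testing, cross-group
# time-effect subtraction, and the direct-influence summary.

#' Metabolite quality control
#'
#' Three filters applied in a fixed order so the report counts each feature
#' once: (1) intensity — the feature must reach `min_intensity` in at least
#' one sample; (2) prevalence — the feature must reach `min_intensity` in at
#' least `min_prevalence` of the samples of EACH group; (3) reproducibility —
#' features with relative standard deviation (sd/mean of positive
#' intensities) above `max_rsd` are dropped.
#'
#' @param table a metabolite [feature_table()].
#' @param min_intensity minimum peak intensity (default 1000).
#' @param min_prevalence per-group prevalence fraction (default 0.20).
#' @param max_rsd maximum relative standard deviation (default 0.20).
#' @param rsd_scope `"pooled"` (all samples, default) or `"per_group"`
#'   (feature dropped if RSD exceeds the cap in any group).
#' @return list with `table` (filtered [feature_table()]) and `report`
#'   (class `qc_report`: counts in/removed/out).
#' @export
metabolite_qc <- function(table, min_intensity = 1000, min_prevalence = 0.20,
                          max_rsd = 0.20, rsd_scope = c("pooled", "per_group")) {
  if (table$layer != "metabolite") stop("metabolite_qc expects the metabolite layer")
  rsd_scope <- match.arg(rsd_scope)
  X <- table$values
  n_in <- ncol(X)
  hit <- X >= min_intensity

  pass_int <- colSums(hit) > 0
  rem_int <- sum(!pass_int)

  grp <- table$samples$group
  prev_ok <- rep(TRUE, n_in)
  for (g in unique(grp)) {
    rows <- grp == g
    prev_ok <- prev_ok & colMeans(hit[rows, , drop = FALSE]) >= min_prevalence
  }
  pass_prev <- pass_int & prev_ok
  rem_prev <- sum(pass_int & !prev_ok)

  rsd_of <- function(rows) {
    apply(X[rows, , drop = FALSE], 2, function(v) {
      v <- v[v > 0]
      if (length(v) < 2) return(0)
      stats::sd(v) / mean(v)
    })
  }
  rsd <- if (rsd_scope == "pooled") {
    rsd_of(rep(TRUE, nrow(X)))
  } else {
    do.call(pmax, lapply(unique(grp), function(g) rsd_of(grp == g)))
  }
  pass_rsd <- pass_prev & rsd <= max_rsd
  rem_rsd <- sum(pass_prev & rsd > max_rsd)

  keep <- which(pass_rsd)
  if (!length(keep)) stop("metabolite QC removed every feature")
  out <- feature_table(X[, keep, drop = FALSE], table$samples, "metabolite")
  report <- structure(list(n_features_in = n_in,
                           n_removed_intensity = rem_int,
                           n_removed_prevalence = rem_prev,
                           n_removed_rsd = rem_rsd,
                           n_features_out = length(keep)),
                      class = "qc_report")
  do_log("metabolite_qc: %d in -> %d out (intensity -%d, prevalence -%d, RSD -%d)",
         n_in, length(keep), rem_int, rem_prev, rem_rsd)
  list(table = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d in; removed: intensity %d, prevalence %d,",
                     " RSD %d; %d out\n"),
              x$n_features_in, x$n_removed_intensity, x$n_removed_prevalence,
              x$n_removed_rsd, x$n_features_out))
  invisible(x)
}

#' Centred log-ratio transform with multiplicative zero replacement
#'
#' Per sample, zeros are replaced by `pseudocount_factor` times the smallest
#' positive value of that sample and the non-zero entries are scaled down
#' multiplicatively so the sample total is preserved; then
#' `y_i = ln x_i - mean_j ln x_j`.  Output rows sum to zero.
#'
#' @param table a [feature_table()] (non-negative values, no all-zero sample).
#' @param pseudocount_factor multiplier on the per-sample minimum positive
#'   value (default 0.65).
#' @return object of class `clr_table` (same shape, real-valued).
#' @export
clr_transform <- function(table, pseudocount_factor = 0.65) {
  X <- table$values
  Y <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    if (all(x == 0)) stop("all-zero sample in CLR input: ", rownames(X)[i])
    z <- x == 0
    if (any(z)) {
      delta <- pseudocount_factor * min(x[!z])
      tot <- sum(x)
      x[!z] <- x[!z] * (tot - sum(z) * delta) / tot
      x[z] <- delta
    }
    lx <- log(x)
    Y[i, ] <- lx - mean(lx)
  }
  structure(list(layer = table$layer, samples = table$samples,
                 features = colnames(Y), values = Y),
            class = "clr_table")
}

# values + samples accessors shared by feature_table / immunity_panel /
# clr_table
.values <- function(x) x$values
.samples <- function(x) x$samples
.is_closed_layer <- function(x) {
  inherits(x, "feature_table") && x$layer %in% REL_LAYERS
}

# per-subject endline - baseline matrix for the paired subjects of one group
.delta_matrix <- function(x, group) {
  md <- .samples(x)
  subs <- paired_subjects(md, group)
  if (!length(subs)) stop("no paired subjects in group ", group)
  md <- md[md$group == group & md$subject_id %in% subs, , drop = FALSE]
  base_id <- md$sample_id[match(paste(subs, "baseline"),
                                paste(md$subject_id, md$timepoint))]
  end_id <- md$sample_id[match(paste(subs, "endline"),
                               paste(md$subject_id, md$timepoint))]
  V <- .values(x)
  D <- V[end_id, , drop = FALSE] - V[base_id, , drop = FALSE]
  rownames(D) <- subs
  attr(D, "base_id") <- base_id
  attr(D, "end_id") <- end_id
  D
}

#' Paired within-group change test per feature
#'
#' For every feature (or immunity indicator), a Wilcoxon signed-rank test on
#' the per-subject endline - baseline differences within one arm.  The
#' reported direction is the sign of the median difference when
#' `p < alpha`, else `"none"`.  `median_change_fraction` is the median of the
#' per-subject relative change `(end - base)/base`, computed on raw values
#' (pass the raw table through `raw` when testing CLR-transformed data).
#'
#' @param x a [feature_table()], [immunity_panel()] or `clr_table`.
#' @param group `"placebo"` or `"probiotic"`.
#' @param alpha significance level for the direction call (default 0.05).
#' @param min_pairs minimum paired subjects (power floor, default 6).
#' @param raw optional table on the raw scale for percent-change reporting.
#' @return data.frame (class `paired_change_result`) with columns `feature`,
#'   `p_value`, `direction`, `median_change_fraction`, `n_pairs` and
#'   attribute `group`.
#' @export
paired_change_test <- function(x, group, alpha = 0.05, min_pairs = 6,
                               raw = NULL) {
  group <- match.arg(group, GROUPS)
  D <- .delta_matrix(x, group)
  if (nrow(D) < min_pairs) {
    stop("fewer than ", min_pairs, " paired subjects in group ", group)
  }
  Draw <- if (is.null(raw)) NULL else .delta_matrix(raw, group)
  Vraw <- if (is.null(raw)) .values(x) else .values(raw)
  base_id <- attr(if (is.null(raw)) D else Draw, "base_id")
  res <- lapply(colnames(D), function(f) {
    d <- D[, f]
    sr <- signed_rank_test(d)
    med <- stats::median(d)
    dir <- if (!is.na(sr$p_value) && sr$p_value < alpha) {
      if (med > 0) "up" else if (med < 0) "down" else "none"
    } else "none"
    base_raw <- Vraw[base_id, f]
    draw <- if (is.null(raw)) d else Draw[, f]
    ok <- base_raw > 0
    mcf <- if (any(ok)) stats::median(draw[ok] / base_raw[ok]) else NA_real_
    data.frame(feature = f, p_value = sr$p_value, direction = dir,
               median_diff = med, median_change_fraction = mcf,
               n_pairs = sr$n_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "group") <- group
  attr(out, "alpha") <- alpha
  class(out) <- c("paired_change_result", "data.frame")
  out
}

#' Cross-group time-effect subtraction
#'
#' Features that changed significantly in the SAME direction in both arms are
#' attributed to time development and classified `time_effect`; features
#' significant in at least one arm but not a shared-direction time effect are
#' `treatment_differential`; everything else is `unchanged`.  With
#' `strict_probiotic_only = TRUE` only probiotic-arm significance can yield
#' `treatment_differential` (placebo-only changes become `unchanged`).
#'
#' @param res_placebo,res_probiotic [paired_change_test()] results over the
#'   same feature universe.
#' @param alpha significance level (default 0.05).
#' @param strict_probiotic_only restrict the differential call to
#'   probiotic-arm significance.
#' @param fdr apply Benjamini-Hochberg adjustment to each arm's p-values
#'   before classification (default FALSE: raw p, as reported in the study
#'   design this emulates).
#' @return data.frame (class `differential_result`): `feature`, `p_placebo`,
#'   `p_probiotic`, `direction_placebo`, `direction_probiotic`,
#'   `classification`.
#' @export
time_effect_subtraction <- function(res_placebo, res_probiotic, alpha = 0.05,
                                    strict_probiotic_only = FALSE,
                                    fdr = FALSE) {
  if (!identical(res_placebo$feature, res_probiotic$feature)) {
    stop("feature universes differ between the two groups")
  }
  p_pla <- res_placebo$p_value
  p_pro <- res_probiotic$p_value
  if (fdr) {
    p_pla <- bh_adjust(p_pla)
    p_pro <- bh_adjust(p_pro)
  }
  sig_pla <- !is.na(p_pla) & p_pla < alpha
  sig_pro <- !is.na(p_pro) & p_pro < alpha
  dir_of <- function(sig, md) {
    ifelse(sig & md > 0, "up", ifelse(sig & md < 0, "down", "none"))
  }
  dir_pla <- dir_of(sig_pla, res_placebo$median_diff)
  dir_pro <- dir_of(sig_pro, res_probiotic$median_diff)
  time_eff <- sig_pla & sig_pro & dir_pla == dir_pro & dir_pla != "none"
  diff <- if (strict_probiotic_only) {
    sig_pro & !time_eff
  } else {
    (sig_pla | sig_pro) & !time_eff
  }
  cls <- ifelse(time_eff, "time_effect",
                ifelse(diff, "treatment_differential", "unchanged"))
  out <- data.frame(feature = res_placebo$feature,
                    p_placebo = p_pla, p_probiotic = p_pro,
                    direction_placebo = dir_pla,
                    direction_probiotic = dir_pro,
                    classification = cls, stringsAsFactors = FALSE)
  class(out) <- c("differential_result", "data.frame")
  do_log("time_effect_subtraction: %d features -> %d time_effect, %d differential",
         nrow(out), sum(time_eff), sum(diff))
  out
}

# mean per-feature relative abundance among probiotic endline samples;
# metabolite intensities are normalised to per-sample proportions first
.mean_endline_proportion <- function(table, group = "probiotic") {
  md <- table$samples
  rows <- md$group == group & md$timepoint == "endline"
  X <- table$values[md$sample_id[rows], , drop = FALSE]
  if (!.is_closed_layer(table)) X <- X / rowSums(X)
  colMeans(X)
}

#' Direct-influence summary
#'
#' The count ratio (differential features / all features) and the effect-size
#' proportion: the summed mean relative abundance of the
#' `treatment_differential` features among probiotic-arm endline samples.
#'
#' @param diff a [time_effect_subtraction()] result.
#' @param table the corresponding raw [feature_table()].
#' @return list (class `influence_summary`): `layer`, `n_differential`,
#'   `n_total`, `count_ratio`, `proportion`.
#' @export
direct_influence_summary <- function(diff, table) {
  feats <- diff$feature[diff$classification == "treatment_differential"]
  mp <- .mean_endline_proportion(table)
  structure(list(layer = table$layer,
                 n_differential = length(feats),
                 n_total = nrow(diff),
                 count_ratio = length(feats) / nrow(diff),
                 proportion = sum(mp[feats])),
            class = "influence_summary")
}

#' @export
print.influence_summary <- function(x, ...) {
  cat(sprintf("<influence_summary> %s: %d/%d features (%.1f%%), proportion %.1f%%\n",
              x$layer, x$n_differential %||% x$n_implicated, x$n_total,
              100 * x$count_ratio, 100 * x$proportion))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
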