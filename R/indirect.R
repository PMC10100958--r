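# The "indirect influence" procedure: per-subject delta correlation of omics
# features with immunity indicators, per-group significance, removal of
# correlations shared by both arms, and the count/proportion summary.

#' Per-subject endline - baseline deltas for one group
#'
#' @param x a [feature_table()], [immunity_panel()] or `clr_table`.
#' @param group `"placebo"` or `"probiotic"`.
#' @return object of class `delta_table`: list with `group`, `subjects`,
#'   `columns`, `values` (subjects x columns matrix of differences).
#' @export
subject_deltas <- function(x, group) {
  group <- match.arg(group, GROUPS)
  D <- .delta_matrix(x, group)
  attr(D, "base_id") <- NULL
  attr(D, "end_id") <- NULL
  structure(list(group = group, subjects = rownames(D),
                 columns = colnames(D), values = D),
            class = "delta_table")
}

#' @export
print.delta_table <- function(x, ...) {
  cat(sprintf("<delta_table> %s: %d subjects x %d columns\n",
              x$group, length(x$subjects), length(x$columns)))
  invisible(x)
}

#' Euclidean distance on per-subject deltas
#'
#' Used for the PERMANOVA on the changes of the immunity indicators; the
#' `standardize` switch scales each indicator's deltas to unit sd first (the
#' study design leaves this unstated, so it is exposed, defaulting to off).
#'
#' @param deltas a [subject_deltas()] result, or several rbound (one per
#'   group) as a list.
#' @param standardize scale each column to unit sd across all subjects.
#' @return list with `subjects`, `groups`, `d` (distance matrix).
#' @export
delta_distance <- function(deltas, standardize = FALSE) {
  if (inherits(deltas, "delta_table")) deltas <- list(deltas)
  V <- do.call(rbind, lapply(deltas, `[[`, "values"))
  groups <- unlist(lapply(deltas, function(d) rep(d$group, length(d$subjects))))
  if (standardize) {
    sds <- apply(V, 2, stats::sd)
    sds[sds == 0] <- 1
    V <- sweep(V, 2, sds, `/`)
  }
  d <- as.matrix(stats::dist(V))
  list(subjects = rownames(V), groups = groups, d = d)
}

#' Delta-correlation screen of one group
#'
#' All feature x indicator Spearman correlations between per-subject omics
#' deltas and immunity-indicator deltas; edges with `p < alpha` are kept,
#' with their sign.  Constant columns are flagged and skipped.  The
#' significance threshold is interpreted as a p-value cut-off (config key
#' `indirect$spearman_threshold_is_p_value`).
#'
#' @param deltas_omics,deltas_immunity [subject_deltas()] of the same group
#'   with identical subject order.
#' @param alpha p-value threshold (default 0.05).
#' @param fdr apply BH adjustment across the grid first (default FALSE).
#' @return data.frame (class `correlation_edges`): `feature`, `indicator`,
#'   `rho`, `p_value`, `sign`, `group`.
#' @export
correlate_group <- function(deltas_omics, deltas_immunity, alpha = 0.05,
                            fdr = FALSE) {
  if (!identical(deltas_omics$subjects, deltas_immunity$subjects)) {
    stop("subject order mismatch between omics and immunity deltas")
  }
  if (!identical(deltas_omics$group, deltas_immunity$group)) {
    stop("delta tables come from different groups")
  }
  g <- spearman_grid(deltas_omics$values, deltas_immunity$values)
  p <- g$p
  if (fdr) p[] <- bh_adjust(as.vector(p))
  n_skip <- sum(is.na(g$rho))
  if (n_skip) do_log("correlate_group: %d constant pairs skipped", n_skip)
  keep <- which(!is.na(p) & p < alpha, arr.ind = TRUE)
  out <- data.frame(
    feature = deltas_omics$columns[keep[, 1]],
    indicator = deltas_immunity$columns[keep[, 2]],
    rho = g$rho[keep], p_value = p[keep],
    sign = ifelse(g$rho[keep] > 0, "+", "-"),
    group = rep(deltas_omics$group, nrow(keep)), stringsAsFactors = FALSE)
  out <- out[order(out$feature, out$indicator), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correlation_edges", "data.frame")
  do_log("correlate_group(%s): %d/%d edges kept at alpha=%g",
         deltas_omics$group, nrow(out), length(p), alpha)
  out
}

edge_key <- function(edges) {
  paste(edges$feature, edges$indicator, edges$sign, sep = "\r")
}

#' Remove correlations shared by both arms
#'
#' Edge identity for the overlap is (feature, indicator, sign): the same
#' positive (or negative) correlation found in both groups is attributed to
#' time and removed; the same pair with opposite signs is kept in both
#' unique sets.
#'
#' @param edges_probiotic,edges_placebo [correlate_group()] results.
#' @return list with `unique_probiotic`, `unique_placebo`, `shared`
#'   (data.frames; `shared` carries the probiotic-side rho/p).
#' @export
remove_shared_edges <- function(edges_probiotic, edges_placebo) {
  k_pro <- edge_key(edges_probiotic)
  k_pla <- edge_key(edges_placebo)
  shared_k <- intersect(k_pro, k_pla)
  list(unique_probiotic = edges_probiotic[!k_pro %in% shared_k, , drop = FALSE],
       unique_placebo = edges_placebo[!k_pla %in% shared_k, , drop = FALSE],
       shared = edges_probiotic[k_pro %in% shared_k, , drop = FALSE])
}

#' Indirect-influence summary for one omics layer
#'
#' Implicated features are those carrying at least one group-unique edge in
#' the probiotic arm (optionally the union of both arms' unique edges);
#' the effect size is their summed mean relative abundance among
#' probiotic-arm endline samples.
#'
#' @param unique_edges the [remove_shared_edges()] result.
#' @param table the layer's raw [feature_table()].
#' @param union_groups also count features implicated only by placebo-unique
#'   edges (default FALSE: probiotic reading).
#' @return list (class `influence_summary`): `layer`, `n_implicated`,
#'   `n_total`, `count_ratio`, `proportion`, `n_edges_probiotic`,
#'   `n_edges_placebo`.
#' @export
indirect_influence_summary <- function(unique_edges, table,
                                       union_groups = FALSE) {
  feats <- unique_edges$unique_probiotic$feature
  if (union_groups) feats <- c(feats, unique_edges$unique_placebo$feature)
  feats <- intersect(unique(feats), table$features)
  mp <- .mean_endline_proportion(table)
  structure(list(layer = table$layer,
                 n_implicated = length(feats),
                 n_total = length(table$features),
                 count_ratio = length(feats) / length(table$features),
                 proportion = sum(mp[feats]),
                 n_edges_probiotic = sum(unique_edges$unique_probiotic$feature
                                         %in% table$features),
                 n_edges_placebo = sum(unique_edges$unique_placebo$feature
                                       %in% table$features)),
            class = "influence_summary")
}
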