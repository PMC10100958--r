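# Alpha/beta diversity, within-group convergence, permutation PERMANOVA.

#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` over the positive entries, with `p_i = x_i / sum x`
#' and the natural logarithm (vegan's convention).
#'
#' @param x non-negative numeric vector with at least one positive entry.
#' @return Shannon index (nats).
#' @export
shannon <- function(x) {
  if (any(x < 0)) stop("negative abundance")
  s <- sum(x)
  if (s <= 0) stop("all-zero abundance vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `BC = sum |x_i - y_i| / sum (x_i + y_i)`, in `[0, 1]`.
#'
#' @param x,y non-negative numeric vectors of equal length, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("negative abundance")
  denom <- sum(x) + sum(y)
  if (denom <= 0) stop("both samples are all-zero")
  sum(abs(x - y)) / denom
}

#' All-pairs Bray-Curtis distance matrix
#'
#' Computes pairwise Bray-Curtis dissimilarities over a sample subset.  The
#' metabolite layer carries raw intensities, which would make Bray-Curtis
#' scale-dependent, so metabolite samples are first normalised to per-sample
#' proportions (logged).
#'
#' @param table a [feature_table()].
#' @param group,timepoint optional filters selecting the sample subset.
#' @return object of class `dist_matrix`: list with `samples` (metadata) and
#'   `d` (symmetric matrix, zero diagonal, sample ids as dimnames).
#' @export
distance_matrix <- function(table, group = NULL, timepoint = NULL) {
  md <- table$samples
  keep <- rep(TRUE, nrow(md))
  if (!is.null(group)) keep <- keep & md$group %in% group
  if (!is.null(timepoint)) keep <- keep & md$timepoint %in% timepoint
  if (sum(keep) < 2L) stop("need at least 2 samples for a distance matrix")
  md <- md[keep, , drop = FALSE]
  X <- table$values[md$sample_id, , drop = FALSE]
  if (table$layer == "metabolite") {
    do_log("distance_matrix: normalising metabolite intensities to proportions")
    rs <- rowSums(X)
    if (any(rs <= 0)) stop("all-zero metabolite sample")
    X <- X / rs
  }
  num <- as.matrix(stats::dist(X, method = "manhattan"))
  s <- rowSums(X)
  den <- outer(s, s, `+`)
  d <- num / den
  diag(d) <- 0
  dimnames(d) <- list(md$sample_id, md$sample_id)
  structure(list(samples = md, d = d), class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d samples, Bray-Curtis in [%.3f, %.3f]\n",
              nrow(x$d), min(x$d[upper.tri(x$d)]), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

# SS_within for label matrix L (N x P, values 1..a) given squared distances
.permanova_F <- function(D2, Lab, ss_total, a, n_per) {
  N <- nrow(D2)
  ss_within <- numeric(ncol(Lab))
  for (g in seq_len(a)) {
    Z <- (Lab == g) * 1
    ss_within <- ss_within + colSums(Z * (D2 %*% Z)) / (2 * n_per[g])
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (N - a))
}

#' Permutation PERMANOVA (one-way, from distances)
#'
#' Anderson's pseudo-F computed directly from the distance matrix:
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `F = (SS_between/(a-1)) / (SS_within/(N-a))`.
#' The p-value is `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)` over
#' uniformly drawn label permutations, or the exact proportion over all `N!`
#' relabellings when `exact = TRUE` (small N only).
#'
#' @param dm a `dist_matrix` from [distance_matrix()], or a plain symmetric
#'   matrix.
#' @param labels group label per sample (character or factor), at least two
#'   groups with two members each.
#' @param n_permutations Monte-Carlo permutations (default 999).
#' @param seed RNG seed for the permutations (required for reproducibility).
#' @param exact enumerate all relabellings instead of sampling (N <= 9).
#' @return list with `pseudo_F`, `p_value`, `n_permutations`, `n_groups`,
#'   `n_samples`.
#' @export
permanova <- function(dm, labels, n_permutations = 999, seed = 1,
                      exact = FALSE) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  N <- nrow(d)
  if (length(labels) != N) stop("labels length must match sample count")
  f <- factor(labels)
  a <- nlevels(f)
  n_per <- as.integer(table(f))
  if (a < 2L) stop("need at least 2 groups")
  if (any(n_per < 2L)) stop("group with fewer than 2 members")
  D2 <- d^2
  ss_total <- sum(D2) / (2 * N)
  lab <- as.integer(f)
  F_obs <- .permanova_F(D2, matrix(lab, ncol = 1), ss_total, a, n_per)
  if (!is.finite(F_obs)) stop("zero within-group variance")
  if (exact) {
    perms <- all_permutations(N)
    Lab <- matrix(lab[t(perms)], nrow = N)      # each column a relabelling
    F_perm <- .permanova_F(D2, Lab, ss_total, a, n_per)
    p <- mean(F_perm >= F_obs - 1e-12)
    return(list(pseudo_F = F_obs, p_value = p,
                n_permutations = nrow(perms), n_groups = a, n_samples = N))
  }
  set.seed(seed)
  Lab <- vapply(seq_len(n_permutations), function(i) lab[sample.int(N)],
                integer(N))
  F_perm <- .permanova_F(D2, Lab, ss_total, a, n_per)
  p <- (1 + sum(F_perm >= F_obs - 1e-12)) / (1 + n_permutations)
  list(pseudo_F = F_obs, p_value = p, n_permutations = n_permutations,
       n_groups = a, n_samples = N)
}

#' Within-group pairwise dissimilarities for one group/timepoint cell
#'
#' Returns the `C(n, 2)` pairwise Bray-Curtis distances among the samples of
#' one group at one timepoint, named by the subject pair
#' (`"subjA:subjB"`, lexicographically ordered) so baseline and endline lists
#' can be paired subject-pair by subject-pair.
#'
#' @param dm a `dist_matrix` covering the cell.
#' @param group,timepoint cell selectors.
#' @return named numeric vector of length `C(n, 2)`.
#' @export
within_group_dissimilarity <- function(dm, group, timepoint) {
  md <- dm$samples
  sel <- md$group == group & md$timepoint == timepoint
  if (sum(sel) < 2L) stop("fewer than 2 samples in cell ", group, "/", timepoint)
  md <- md[sel, , drop = FALSE]
  md <- md[order(md$subject_id), , drop = FALSE]
  n <- nrow(md)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  vals <- dm$d[md$sample_id, md$sample_id][upper.tri(matrix(0, n, n))]
  names(vals) <- paste(md$subject_id[idx[, 1]], md$subject_id[idx[, 2]],
                       sep = ":")
  vals
}

#' Convergence tests on within-group dissimilarity
#'
#' The convergence signature is a decrease of within-group Bray-Curtis
#' dissimilarity from baseline to endline.  Between the two arms at each
#' timepoint a Wilcoxon rank-sum test compares the two dissimilarity lists;
#' within each arm a Wilcoxon signed-rank test pairs each subject-pair's
#' baseline distance with the same subject-pair's endline distance.
#'
#' @param dm_baseline,dm_endline `dist_matrix` objects for the two timepoints
#'   (both containing both groups).
#' @return object of class `convergence_comparison`: list with `within`
#'   (per group/timepoint named distance vectors), `rank_sum` (data.frame
#'   timepoint, statistic, p_value), `signed_rank` (data.frame group,
#'   statistic, p_value, direction, median_change).
#' @export
convergence_tests <- function(dm_baseline, dm_endline) {
  within <- list()
  for (g in GROUPS) {
    within[[g]] <- list(
      baseline = within_group_dissimilarity(dm_baseline, g, "baseline"),
      endline = within_group_dissimilarity(dm_endline, g, "endline"))
  }
  rank_sum <- do.call(rbind, lapply(TIMEPOINTS, function(tp) {
    rs <- rank_sum_test(within[["placebo"]][[tp]], within[["probiotic"]][[tp]])
    data.frame(timepoint = tp, statistic = rs$statistic,
               p_value = rs$p_value, stringsAsFactors = FALSE)
  }))
  signed_rank <- do.call(rbind, lapply(GROUPS, function(g) {
    b <- within[[g]]$baseline
    e <- within[[g]]$endline
    if (!setequal(names(b), names(e))) {
      stop("subject-pair sets differ across timepoints for group ", g)
    }
    d <- e[names(b)] - b
    sr <- signed_rank_test(d)
    med <- stats::median(d)
    dir <- if (sr$p_value < 0.05) { if (med < 0) "down" else "up" } else "none"
    data.frame(group = g, statistic = sr$statistic, p_value = sr$p_value,
               direction = dir, median_change = med, stringsAsFactors = FALSE)
  }))
  structure(list(within = within, rank_sum = rank_sum,
                 signed_rank = signed_rank),
            class = "convergence_comparison")
}

#' @export
print.convergence_comparison <- function(x, ...) {
  cat("<convergence_comparison>\n  rank-sum (between groups):\n")
  print(x$rank_sum, row.names = FALSE)
  cat("  signed-rank (baseline vs endline):\n")
  print(x$signed_rank, row.names = FALSE)
  invisible(x)
}
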