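# From-scratch nonparametric kernels.  These are deliberately independent of
# stats::wilcox.test / cor.test so the test suite can check them against
# exhaustive enumeration and against the base-R implementations as oracles.

#' All permutations of 1..n
#'
#' @param n integer (n <= 9; 9! rows).
#' @return integer matrix, n! rows, each row one permutation.
#' @keywords internal
all_permutations <- function(n) {
  if (n > 9L) stop("refusing to enumerate more than 9! permutations")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[((i - 1L) * nrow(sub) + 1L):(i * nrow(sub)), ] <-
      cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  out
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided one-sample signed-rank test.  Zero differences are dropped
#' (Wilcoxon's original treatment).  The null distribution is exact — computed
#' by dynamic programming over all `2^n` sign assignments, tie-aware through
#' midranks — when the number of non-zero differences is at most
#' `exact_limit`; beyond that a normal approximation with tie correction is
#' used (no continuity correction).  The two-sided p-value is
#' `P(|W - mu| >= |w_obs - mu|)` under the null, matching brute-force
#' enumeration.
#'
#' @param d numeric vector of paired differences (endline - baseline).
#' @param exact_limit switch-over size for the exact null (default 25).
#' @return list with `statistic` (W+, sum of positive ranks), `p_value`,
#'   `n_used` (non-zero differences), `method`.
#' @export
signed_rank_test <- function(d, exact_limit = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_limit) {
    # exact distribution of 2*W over sign assignments (integer midranks * 2)
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    counts <- numeric(tot + 1)          # index k+1 <-> 2W = k
    counts[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), counts[seq_len(tot + 1 - rr)])
      counts <- counts + shifted
    }
    w2 <- round(2 * w)
    dev <- abs(seq(0, tot) - tot / 2)
    p <- sum(counts[dev >= abs(w2 - tot / 2) - 1e-9]) / 2^n
    return(list(statistic = w, p_value = p, n_used = n, method = "exact"))
  }
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sigma2)
  list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       n_used = n, method = "normal")
}

#' Wilcoxon rank-sum test (two independent samples)
#'
#' Thin wrapper over [stats::wilcox.test()] with the normal approximation and
#' continuity correction, used for between-group comparisons of dissimilarity
#' lists and abundances.
#'
#' @param x,y numeric vectors.
#' @return list with `statistic` (W) and `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Spearman rank correlation with t-approximation or exact p-value
#'
#' `rho` is the Pearson correlation of midranks (tie-aware).  The default
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom; with `exact = TRUE` (allowed for `n <= 9`) the
#' two-sided p is computed by full enumeration of all `n!` rank permutations:
#' `P(|rho_perm| >= |rho_obs|)`.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param exact logical; exact permutation null (requires `n <= 9`).
#' @return list with `rho`, `p_value`, `n`, `method`.  Constant input gives
#'   `rho = NA` and `p_value = NA` (callers flag and skip such edges).
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("spearman_cor needs n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "constant"))
  }
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 9L) stop("exact Spearman enumeration limited to n <= 9")
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(ix) stats::cor(rx, ry[ix]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    return(list(rho = rho, p_value = p, n = n, method = "exact"))
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, method = "t")
}

# vectorised spearman grid: columns of X vs columns of Y (same row order);
# returns list of rho and p matrices (t approximation), NA for constant cols
spearman_grid <- function(X, Y) {
  n <- nrow(X)
  RX <- apply(X, 2L, rank)
  RY <- apply(Y, 2L, rank)
  sdx <- apply(RX, 2L, stats::sd)
  sdy <- apply(RY, 2L, stats::sd)
  RX[, sdx == 0] <- NA
  RY[, sdy == 0] <- NA
  rho <- suppressWarnings(stats::cor(RX, RY))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1 - 1e-15] <- 0
  p[is.na(rho)] <- NA
  list(rho = rho, p = p)
}

# Benjamini-Hochberg, used behind the optional fdr switches
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
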