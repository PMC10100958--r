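test_that("shannon matches closed forms and a brute-force oracle", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(c(1, 0, 0)), 0)
  set.seed(31)
  for (i in 1:5) {
    x <- runif(10)
    p <- x / sum(x)
    expect_equal(shannon(x), -sum(p * log(p)))     # term-by-term oracle
  }
  # maximal at the uniform vector among vectors of the same support size
  for (i in 1:20) {
    x <- rexp(7)
    expect_lte(shannon(x), shannon(rep(1, 7)) + 1e-12)
  }
  expect_error(shannon(c(0, 0)), "all-zero")
})

test_that("bray_curtis matches hand arithmetic and is a bounded semimetric", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(1, 2, 3), c(3, 2, 1)), 4 / 12)
  set.seed(8)
  for (i in 1:25) {
    x <- rexp(6) * rbinom(6, 1, 0.7)
    y <- rexp(6) * rbinom(6, 1, 0.7)
    if (sum(x) + sum(y) == 0) next
    b <- bray_curtis(x, y)
    expect_equal(b, bray_curtis(y, x))
    expect_gte(b, 0); expect_lte(b, 1)
  }
  expect_error(bray_curtis(1:3, 1:4), "length mismatch")
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
})

test_that("distance_matrix equals pairwise calls and respects sample order", {
  md <- toy_metadata(2)
  set.seed(40)
  vals <- matrix(rexp(8 * 6), 8, 6, dimnames = list(md$sample_id, paste0("f", 1:6)))
  ft <- feature_table(vals, md, "metabolite")
  dm <- distance_matrix(ft)
  for (i in 1:3) for (j in (i + 1):4) {
    # metabolite layer is normalised to proportions first
    xi <- vals[i, ] / sum(vals[i, ]); xj <- vals[j, ] / sum(vals[j, ])
    expect_equal(dm$d[i, j], bray_curtis(xi, xj))
  }
  expect_true(isSymmetric(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 8))

  # permuting the sample order permutes the matrix
  perm <- sample(8)
  ft2 <- feature_table(vals[perm, ], md[perm, ], "metabolite")
  dm2 <- distance_matrix(ft2)
  ids <- md$sample_id
  expect_equal(dm2$d[ids, ids], dm$d[ids, ids])

  # identical samples are at distance zero
  vals[2, ] <- vals[1, ]
  dmi <- distance_matrix(feature_table(vals, md, "metabolite"))
  expect_equal(dmi$d[1, 2], 0)
  expect_error(distance_matrix(ft, group = "placebo", timepoint = "missing"),
               "at least 2 samples")
})

test_that("permanova pseudo-F and exact p equal full label enumeration", {
  lab <- rep(c("a", "b"), each = 3)
  set.seed(17)
  for (rep in 1:3) {
    X <- matrix(rnorm(6 * 4), 6)
    d <- as.matrix(dist(X))
    res <- permanova(d, lab, exact = TRUE)

    # independent oracle: direct SS formulas + enumeration of all 6! labelings
    F_of <- function(l) {
      N <- 6; a <- 2
      sst <- sum(d[upper.tri(d)]^2) / N
      ssw <- 0
      for (g in unique(l)) {
        idx <- which(l == g)
        sub <- d[idx, idx]
        ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
      }
      ((sst - ssw) / (a - 1)) / (ssw / (N - a))
    }
    expect_equal(res$pseudo_F, F_of(lab))
    if (requireNamespace("vegan", quietly = TRUE)) {
      ad <- vegan::adonis2(as.dist(d) ~ lab, permutations = 2)
      expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
    }
    Fs <- apply(perms_oracle(6), 1, function(ix) F_of(lab[ix]))
    expect_equal(res$p_value, mean(Fs >= res$pseudo_F - 1e-12))
  }
})

test_that("permanova handles exchangeable and maximally separated inputs", {
  # all off-diagonal distances equal: every relabelling gives the same F
  d <- matrix(1, 6, 6); diag(d) <- 0
  res <- permanova(d, rep(c("a", "b"), each = 3), exact = TRUE)
  expect_equal(res$p_value, 1)

  # two tight clouds far apart: smallest attainable Monte-Carlo p
  X <- rbind(matrix(rnorm(10 * 3, 0, 0.01), 10),
             matrix(rnorm(10 * 3, 50, 0.01), 10))
  d <- as.matrix(dist(X))
  res <- permanova(d, rep(c("a", "b"), each = 10), n_permutations = 199,
                   seed = 5)
  expect_equal(res$p_value, 1 / 200)

  expect_error(permanova(d, c(rep("a", 19), "b")), "fewer than 2")
  d0 <- matrix(0, 6, 6)
  expect_error(permanova(d0, rep(c("a", "b"), each = 3)),
               "zero within-group variance")
})

test_that("within-group dissimilarity lists match direct matrix lookup", {
  co <- generate_cohort(small_config(seed = 21, n_subjects_per_group = 5))
  dm <- distance_matrix(co$tables$bacteria, timepoint = "baseline")
  w <- within_group_dissimilarity(dm, "placebo", "baseline")
  expect_length(w, choose(5, 2))
  for (k in seq_along(w)) {
    pair <- strsplit(names(w)[k], ":", fixed = TRUE)[[1]]
    ids <- paste0(pair, "_B")
    expect_equal(unname(w[k]), dm$d[ids[1], ids[2]])
  }
  co45 <- generate_cohort(small_config(seed = 22, n_subjects_per_group = 45))
  dm45 <- distance_matrix(co45$tables$fungi, timepoint = "endline")
  expect_length(within_group_dissimilarity(dm45, "probiotic", "endline"), 990L)
})

test_that("convergence tests: degenerate equality and group-swap symmetry", {
  co <- generate_cohort(small_config(seed = 30, n_subjects_per_group = 6))
  ft <- co$tables$bacteria
  # force endline == baseline: all signed-rank differences are zero
  vals <- ft$values
  md <- ft$samples
  e_ids <- md$sample_id[md$timepoint == "endline"]
  b_ids <- sub("_E$", "_B", e_ids)
  vals[e_ids, ] <- vals[b_ids, ]
  ft_eq <- feature_table(vals, md, "bacteria")
  cv <- convergence_tests(distance_matrix(ft_eq, timepoint = "baseline"),
                          distance_matrix(ft_eq, timepoint = "endline"))
  expect_equal(cv$signed_rank$p_value, c(1, 1))
  expect_equal(cv$signed_rank$direction, c("none", "none"))

  # swapping the group labels swaps the roles, p-values unchanged
  md_sw <- md
  md_sw$group <- ifelse(md$group == "placebo", "probiotic", "placebo")
  ft_sw <- feature_table(ft$values, md_sw, "bacteria")
  cv1 <- convergence_tests(distance_matrix(ft, timepoint = "baseline"),
                           distance_matrix(ft, timepoint = "endline"))
  cv2 <- convergence_tests(distance_matrix(ft_sw, timepoint = "baseline"),
                           distance_matrix(ft_sw, timepoint = "endline"))
  expect_equal(cv1$rank_sum$p_value, cv2$rank_sum$p_value)
  expect_equal(
    cv1$signed_rank$p_value[cv1$signed_rank$group == "placebo"],
    cv2$signed_rank$p_value[cv2$signed_rank$group == "probiotic"])
})
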