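test_that("metabolite QC applies intensity, per-group prevalence and RSD rules", {
  md <- toy_metadata(10)   # 20 placebo + 20 probiotic samples
  n <- nrow(md)
  pla <- md$group == "placebo"
  set.seed(60)
  vals <- matrix(5000 * exp(rnorm(n * 4, 0, 0.05)), n, 4)
  colnames(vals) <- c("ok", "low_everywhere", "low_in_probiotic", "noisy")
  vals[, "low_everywhere"] <- 500
  # >= 1000 in 25% of placebo but only 10% of probiotic samples
  vals[, "low_in_probiotic"] <- 100
  vals[pla, "low_in_probiotic"][1:5] <- 1500
  vals[!pla, "low_in_probiotic"][1:2] <- 1500
  vals[, "noisy"] <- 2000 * exp(rnorm(n, 0, 0.8))
  ft <- toy_table(vals, md)
  out <- metabolite_qc(ft)
  expect_identical(out$table$features, "ok")
  expect_equal(out$report$n_removed_intensity, 1L)
  expect_equal(out$report$n_removed_prevalence, 1L)
  expect_equal(out$report$n_removed_rsd, 1L)
  expect_equal(out$report$n_features_out,
               out$report$n_features_in - out$report$n_removed_intensity -
                 out$report$n_removed_prevalence - out$report$n_removed_rsd)
  # a constant positive feature has RSD 0 and is retained
  const <- toy_table(matrix(1500, nrow(md), 2,
                            dimnames = list(NULL, c("c1", "c2"))), md)
  expect_setequal(metabolite_qc(const)$table$features, c("c1", "c2"))
  # only the metabolite layer is accepted
  closed <- toy_table(matrix(0.5, 4, 2, dimnames = list(NULL, c("x", "y"))),
                      toy_metadata(1), layer = "bacteria")
  expect_error(metabolite_qc(closed), "metabolite layer")
})

test_that("metabolite QC RSD filter matches per-feature hand arithmetic", {
  md <- toy_metadata(5)
  set.seed(61)
  vals <- matrix(2000 * exp(rnorm(20 * 20, 0, runif(20, 0.05, 0.5))), 20, 20,
                 byrow = TRUE)
  colnames(vals) <- sprintf("m%02d", 1:20)
  ft <- toy_table(vals, md)
  out <- metabolite_qc(ft, min_intensity = 1, min_prevalence = 0)
  rsd_hand <- apply(vals, 2, function(v) sd(v) / mean(v))   # oracle
  expect_setequal(out$table$features, names(rsd_hand)[rsd_hand <= 0.20])
})

test_that("clr transform: constant composition, scale invariance, zero policy", {
  md <- toy_metadata(1)
  ones <- toy_table(matrix(1, 4, 3, dimnames = list(NULL, c("a", "b", "c"))), md)
  expect_equal(unname(clr_transform(ones)$values), matrix(0, 4, 3))

  set.seed(62)
  x <- matrix(rexp(4 * 8) + 0.01, 4, 8, dimnames = list(NULL, letters[1:8]))
  t1 <- clr_transform(toy_table(x, md))
  t2 <- clr_transform(toy_table(x * 37.5, md))
  expect_equal(t1$values, t2$values)                       # clr(c x) = clr(x)
  expect_true(all(abs(rowSums(t1$values)) < 1e-12))
  expect_equal(t1$values[1, ], log(x[1, ]) - mean(log(x[1, ])))  # formula oracle

  # multiplicative zero replacement: x = (0, 2, 2), delta = 0.65 * 2
  xz <- matrix(c(0, 2, 2), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  md1 <- one_sample_md()
  ftz <- feature_table(xz, md1, "metabolite")
  got <- clr_transform(ftz)$values[1, ]
  delta <- 0.65 * 2
  imp <- c(delta, 2 * (4 - delta) / 4, 2 * (4 - delta) / 4)
  expect_equal(unname(got), log(imp) - mean(log(imp)))

  xall0 <- matrix(0, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(clr_transform(feature_table(xall0, md1, "metabolite")),
               "all-zero")
})

test_that("signed-rank p equals exhaustive enumeration over sign patterns", {
  set.seed(63)
  cases <- list(round(rnorm(8), 2), rnorm(10),
                c(1.5, 1.5, -1.5, 2, 3, -3, 4, 0.5),      # heavy ties
                c(rep(0.5, 4), rep(-0.5, 3), 1.2, 2.2))
  for (d in cases) {
    got <- signed_rank_test(d)
    d1 <- d[d != 0]
    n <- length(d1)
    r <- rank(abs(d1))
    mu <- sum(r) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))  # 2^n oracle
    W <- signs %*% r
    w_obs <- sum(r[d1 > 0])
    p_oracle <- mean(abs(W - mu) >= abs(w_obs - mu) - 1e-9)
    expect_equal(got$p_value, p_oracle)
  }
  # degenerate and extreme cases
  expect_equal(signed_rank_test(rep(0, 6))$p_value, 1)
  ex <- signed_rank_test(rep(1, 20))
  expect_equal(ex$p_value, 2 / 2^20)
  # matches stats::wilcox.test in the tie-free exact regime
  set.seed(64)
  d <- rnorm(12)
  expect_equal(signed_rank_test(d)$p_value,
               wilcox.test(d, exact = TRUE)$p.value)
})

test_that("paired change test: degenerate input, directions, percent change", {
  co <- generate_cohort(small_config(seed = 65, n_subjects_per_group = 8))
  ft <- co$tables$bacteria
  vals <- ft$values
  md <- ft$samples
  e_ids <- md$sample_id[md$timepoint == "endline"]
  vals[e_ids, ] <- vals[sub("_E$", "_B", e_ids), ]
  res <- paired_change_test(feature_table(vals, md, "bacteria"), "placebo")
  expect_true(all(res$p_value == 1))
  expect_true(all(res$direction == "none"))

  # all endline values 1.5x baseline: direction up, median change 0.5
  md2 <- toy_metadata(8)
  base <- matrix(rexp(16 * 3) + 0.1, 16, 3, dimnames = list(NULL, c("a", "b", "c")))
  v2 <- matrix(0, 32, 3, dimnames = list(md2$sample_id, c("a", "b", "c")))
  v2[md2$timepoint == "baseline", ] <- base
  v2[md2$timepoint == "endline", ] <- base * 1.5
  res2 <- paired_change_test(toy_table(v2, md2), "probiotic")
  expect_true(all(res2$direction == "up"))
  expect_equal(res2$median_change_fraction, rep(0.5, 3))

  expect_error(paired_change_test(toy_table(v2, md2), "placebo",
                                  min_pairs = 10), "fewer than 10")
})

test_that("time-effect subtraction classifies per the stated rule", {
  mk <- function(p, md) data.frame(feature = sprintf("f%d", seq_along(p)),
                                   p_value = p, direction = "x",
                                   median_diff = md,
                                   median_change_fraction = md, n_pairs = 20,
                                   stringsAsFactors = FALSE)
  # f1: both up -> time_effect; f2: probiotic only -> differential;
  # f3: opposite directions -> differential; f4: placebo only -> differential;
  # f5: nothing -> unchanged
  pla <- mk(c(0.01, 0.50, 0.02, 0.03, 0.60), c(1, 1, 1, -1, 1))
  pro <- mk(c(0.02, 0.01, 0.01, 0.50, 0.70), c(1, 1, -1, -1, 1))
  cls <- time_effect_subtraction(pla, pro)$classification
  expect_equal(cls, c("time_effect", "treatment_differential",
                      "treatment_differential", "treatment_differential",
                      "unchanged"))
  # strict mode: placebo-only significance no longer counts
  cls_s <- time_effect_subtraction(pla, pro,
                                   strict_probiotic_only = TRUE)$classification
  expect_equal(cls_s[4], "unchanged")
  # time_effect is symmetric in the group roles
  cls_sw <- time_effect_subtraction(pro, pla)$classification
  expect_equal(cls_sw == "time_effect", cls == "time_effect")
  pro_bad <- pro; pro_bad$feature[1] <- "zzz"
  expect_error(time_effect_subtraction(pla, pro_bad), "universes differ")
})

test_that("direct influence summary sums known abundances", {
  md <- toy_metadata(3)
  set.seed(66)
  vals <- matrix(rexp(12 * 10), 12, 10, dimnames = list(NULL, paste0("f", 1:10)))
  vals <- vals / rowSums(vals)
  ft <- toy_table(vals, md, layer = "bacteria")
  mk_diff <- function(cls) {
    structure(data.frame(feature = paste0("f", 1:10), p_placebo = 1,
                         p_probiotic = 1, direction_placebo = "none",
                         direction_probiotic = "none", classification = cls,
                         stringsAsFactors = FALSE),
              class = c("differential_result", "data.frame"))
  }
  none <- direct_influence_summary(mk_diff(rep("unchanged", 10)), ft)
  expect_equal(none$count_ratio, 0); expect_equal(none$proportion, 0)
  all_d <- direct_influence_summary(mk_diff(rep("treatment_differential", 10)), ft)
  expect_equal(all_d$count_ratio, 1)
  expect_equal(all_d$proportion, 1, tolerance = 1e-9)
  cls <- rep("unchanged", 10); cls[c(2, 5, 9)] <- "treatment_differential"
  part <- direct_influence_summary(mk_diff(cls), ft)
  rows <- md$group == "probiotic" & md$timepoint == "endline"
  hand <- sum(colMeans(ft$values[md$sample_id[rows], c("f2", "f5", "f9")]))
  expect_equal(part$proportion, hand)
})

test_that("null cohorts yield near-nominal treatment_differential rates", {
  seeds <- draw_seeds(404, 8)
  fracs <- vapply(seeds, function(s) {
    co <- generate_cohort(null_config(seed = s, n = 20))
    res <- lapply(setNames(c("placebo", "probiotic"),
                           c("placebo", "probiotic")), function(g)
      paired_change_test(co$tables$bacteria, g))
    diff <- time_effect_subtraction(res$placebo, res$probiotic)
    mean(diff$classification == "treatment_differential")
  }, 0)
  # two-arm testing at alpha=0.05: expected ~1-(1-a)^2 ~ 0.0975
  expect_lt(mean(fracs), 2 * 0.05 + 0.04)
})
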