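mk_callset <- function(keys, subject = "S1", timepoint = "baseline") {
  suffix <- if (timepoint == "baseline") "_B" else "_E"
  snv_callset(one_sample_md(paste0(subject, suffix), subject, "placebo",
                            timepoint), keys)
}

rand_keys <- function(n, seed) {
  set.seed(seed)
  sgb <- sample(sprintf("SGB%02d", 1:4), n, replace = TRUE)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  unique(snv_key(sgb, paste0(sgb, "_c1"), sample.int(1e5, n), ref, alt))
}

test_that("host temporal changes equal brute-force membership scans", {
  a <- mk_callset("SGB01|SGB01_c1|5|A>G")
  expect_equal(nrow(host_temporal_changes(a, mk_callset(a$calls,
                                                        timepoint = "endline"))), 0L)
  b <- mk_callset(c(a$calls, "SGB01|SGB01_c1|9|C>T"), timepoint = "endline")
  ch <- host_temporal_changes(a, b)
  expect_equal(ch$key, "SGB01|SGB01_c1|9|C>T")
  expect_equal(ch$direction, "gained")

  for (seed in 1:4) {
    u <- rand_keys(100, seed)
    base <- sample(u, 60); end <- sample(u, 60)
    ch <- host_temporal_changes(mk_callset(base),
                                mk_callset(end, timepoint = "endline"))
    # oracle: per-key membership scan
    for (k in u) {
      in_b <- k %in% base; in_e <- k %in% end
      row <- ch[ch$key == k, ]
      if (in_b == in_e) expect_equal(nrow(row), 0L)
      else expect_equal(row$direction, if (in_e) "gained" else "lost")
    }
  }
  expect_error(host_temporal_changes(a, mk_callset("x", subject = "S2")),
               "different subjects")
  expect_error(host_temporal_changes(a, a), "baseline and one endline")
})

test_that("prevalence filter is inclusive at the 30% boundary", {
  key <- "SGB01|SGB01_c1|5|A>G"
  mk_changes <- function(n_hit) data.frame(
    subject_id = sprintf("S%02d", seq_len(n_hit)), key = key,
    direction = "gained", group = "placebo", stringsAsFactors = FALSE)
  kept3 <- group_candidate_snvs(mk_changes(3), "placebo", n_subjects = 10)
  expect_equal(kept3$snvs$key, key)
  expect_equal(kept3$snvs$fraction, 0.3)
  kept2 <- group_candidate_snvs(mk_changes(2), "placebo", n_subjects = 10)
  expect_equal(nrow(kept2$snvs), 0L)
  # direction scope
  lost <- transform(mk_changes(5), direction = "lost")
  expect_equal(nrow(group_candidate_snvs(lost, "placebo", 10,
                                         direction_scope = "gained")$snvs), 0L)
  expect_equal(nrow(group_candidate_snvs(lost, "placebo", 10)$snvs), 1L)
  expect_error(group_candidate_snvs(mk_changes(1), "placebo", 0), "empty group")
})

test_that("venn subtraction equals brute-force set algebra and partitions", {
  mk_gs <- function(keys, group) structure(
    list(group = group,
         snvs = data.frame(key = keys, n_subjects = 5, fraction = 0.5,
                           stringsAsFactors = FALSE),
         n_group_subjects = 10),
    class = "group_snv_set")
  for (seed in 1:5) {
    u <- rand_keys(200, seed + 10)
    a <- sample(u, 80); b <- sample(u, 80)
    res <- venn_subtract(mk_gs(a, "probiotic"), mk_gs(b, "placebo"))
    expect_setequal(res$unique_probiotic, setdiff(a, b))
    expect_setequal(res$unique_placebo, setdiff(b, a))
    expect_setequal(res$shared, intersect(a, b))
    # pairwise disjoint partition of the union
    expect_length(intersect(res$unique_probiotic, res$unique_placebo), 0L)
    expect_length(intersect(res$shared,
                            c(res$unique_probiotic, res$unique_placebo)), 0L)
    expect_setequal(c(res$unique_probiotic, res$unique_placebo, res$shared),
                    union(a, b))
  }
  r0 <- venn_subtract(mk_gs(c("k1", "k2"), "probiotic"),
                      mk_gs(c("k1", "k2"), "placebo"))
  expect_length(r0$unique_probiotic, 0L)
  expect_length(r0$unique_placebo, 0L)
})

test_that("species categorisation counts, ranks and abundances correctly", {
  map <- setNames(sprintf("Species %s", LETTERS[1:4]), sprintf("SGB%02d", 1:4))
  mk_res <- function(pro, pla) structure(
    list(unique_probiotic = pro, unique_placebo = pla, shared = character(0)),
    class = "attribution_result")

  one <- mk_res(snv_key("SGB01", "SGB01_c1", 1:3, "A", "G"), character(0))
  tab <- species_categorize(one, map)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$rank_probiotic, 1L)
  expect_true(is.na(tab$rank_placebo))

  # dense rank with ties
  pro <- c(snv_key("SGB01", "SGB01_c1", 1:2, "A", "G"),
           snv_key("SGB02", "SGB02_c1", 1:2, "A", "G"),
           snv_key("SGB03", "SGB03_c1", 1, "A", "G"))
  tied <- species_categorize(mk_res(pro, character(0)), map)
  rk <- setNames(tied$rank_probiotic, tied$species)
  expect_equal(unname(rk[c("Species A", "Species B")]), c(1L, 1L))
  expect_equal(unname(rk["Species C"]), 2L)

  # random assignment vs table() oracle
  for (seed in 1:3) {
    u <- rand_keys(120, seed + 40)
    pro <- sample(u, 50); pla <- setdiff(u, pro)
    res <- species_categorize(mk_res(pro, pla), map)
    sp_of <- function(keys) unname(map[sub("\\|.*", "", keys)])
    oracle_pro <- table(sp_of(pro))
    for (s in names(oracle_pro)) {
      expect_equal(res$n_probiotic[res$species == s],
                   unname(as.integer(oracle_pro[s])))
    }
    expect_equal(sum(res$n_sum), 120L)
  }
  expect_error(species_categorize(one, map[-1]), "unmapped sgb_id")
})

test_that("SNV-immunity association recovers a planted coupling and skips constants", {
  co <- generate_cohort(small_config(
    seed = 83, n_subjects_per_group = 45,
    snv_group_rate = c(placebo = 2, probiotic = 1),
    snv_background_rate = 0.02, snv_immunity_coupling = 1.5))
  changes <- cohort_temporal_changes(co$snv, co$metadata)
  cands <- lapply(setNames(c("probiotic", "placebo"),
                           c("probiotic", "placebo")), function(g)
    group_candidate_snvs(changes, g, n_subjects = 45))
  res <- venn_subtract(cands$probiotic, cands$placebo)
  imm_deltas <- lapply(setNames(c("placebo", "probiotic"),
                                c("placebo", "probiotic")), function(g)
    subject_deltas(co$immunity, g))
  si <- correlate_snv_immunity(res, changes, imm_deltas,
                               co$immunity$categories)
  planted <- co$truth$snv_immunity
  hit <- si$edges[si$edges$key == planted$key &
                    si$edges$indicator == planted$indicator, ]
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$group, "probiotic")

  # alpha = 0 keeps nothing
  si0 <- correlate_snv_immunity(res, changes, imm_deltas,
                                co$immunity$categories, alpha = 0)
  expect_equal(nrow(si0$edges), 0L)
  expect_true(all(si0$summary$n_snvs == 0))
})
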