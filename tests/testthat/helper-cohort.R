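# Shared fixtures, built in code at test time.

# metadata for n subjects per group, both timepoints
toy_metadata <- function(n_per_group = 3) {
  subs <- c(sprintf("PLA%03d", seq_len(n_per_group)),
            sprintf("PRO%03d", seq_len(n_per_group)))
  grp <- rep(c("placebo", "probiotic"), each = n_per_group)
  data.frame(
    sample_id = paste0(rep(subs, each = 2), c("_B", "_E")),
    subject_id = rep(subs, each = 2),
    group = rep(grp, each = 2),
    timepoint = rep(c("baseline", "endline"), times = 2 * n_per_group),
    stringsAsFactors = FALSE)
}

# feature table with explicit values; rows are sample ids of toy_metadata
toy_table <- function(values, md = NULL, layer = "metabolite") {
  if (is.null(md)) md <- toy_metadata(nrow(values) / 4)
  rownames(values) <- md$sample_id
  feature_table(values, md, layer)
}

# small fast cohort config; override anything via ...
small_config <- function(seed = 1, ...) {
  over <- list(...)
  args <- list(
    n_subjects_per_group = 10,
    n_features = c(bacteria = 50, fungi = 8, "function" = 8, metabolite = 20),
    convergence_factor = c(placebo = 0, probiotic = 0),
    n_linked_pairs = 0, n_shared_pairs = 0,
    n_drift_features = 0, n_shift_features = 0,
    n_sgbs = 4, snv_group_rate = c(placebo = 1, probiotic = 0.5),
    snv_shared_rate = 0.5, snv_background_rate = 0.05,
    seed = seed)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

# null configuration: no planted effects at all
null_config <- function(seed = 1, n = 10, ...) {
  small_config(seed = seed, n_subjects_per_group = n,
               snv_group_rate = c(placebo = 0, probiotic = 0),
               snv_shared_rate = 0, snv_background_rate = 0,
               snv_immunity_coupling = 0, ...)
}

# independent sub-seed streams: never reuse a data seed for a permutation
# seed (doing so couples the permutations to the data)
draw_seeds <- function(master, n) {
  set.seed(master)
  sample.int(2^30, n)
}

# brute-force permutation generator (independent of the package's)
perms_oracle <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- perms_oracle(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(seq_len(n)[-i][sub], nrow(sub)))
  }))
}

# minimal VCF writer for hand-built records
write_toy_vcf <- function(path, records) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               records), path)
}

one_sample_md <- function(sample_id = "S1_B", subject = "S1",
                          group = "placebo", timepoint = "baseline") {
  data.frame(sample_id = sample_id, subject_id = subject, group = group,
             timepoint = timepoint, stringsAsFactors = FALSE)
}
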