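# Synthetic two-arm, two-timepoint cohort with planted, recorded effects.
# Every downstream stage of the pipeline is validated against the ground
# truth this generator records.

#' Build a synthetic-cohort configuration
#'
#' Defaults state the emulated world: 45 subjects per arm (the study design),
#' four omics layers with log-normal abundance profiles and subject random
#' effects, 69 immunity indicators (34 cytokine / 29 CBC / 6 lymphocyte),
#' centroid-shrinkage convergence in the probiotic arm, planted
#' delta-correlation pairs, and per-host SNV gain/loss processes with a
#' shared background rate plus arm-specific planted rates
#' (placebo > probiotic, the study's qualitative headline).
#'
#' @param n_subjects_per_group subjects per arm (default 45).
#' @param n_features named integer vector: features per omics layer.
#' @param n_indicators immunity indicators (default 69).
#' @param indicator_split named counts per category; scaled to
#'   `n_indicators` when they disagree.
#' @param convergence_factor kappa per group in \[0, 1\]: fractional shrinkage
#'   of endline samples toward the group endline centroid (0 = none).
#' @param n_linked_pairs planted probiotic-arm feature-indicator
#'   delta-correlations (bacteria layer).
#' @param n_shared_pairs planted both-arm, same-sign delta-correlations
#'   (removed downstream as time effects).
#' @param rho_link target correlation of the planted bivariate-normal deltas.
#' @param n_drift_features,drift_effect per-layer features given a common
#'   temporal drift in both arms, in units of the within-subject log-sd.
#' @param n_shift_features,shift_effect per-layer features shifted in the
#'   probiotic arm only (the planted "direct influence").
#' @param n_sgbs species-level genome bins carrying the SNV catalogue.
#' @param snv_group_rate expected planted group-unique SNV changes per SGB,
#'   per group (count = round(rate * n_sgbs)).
#' @param snv_shared_rate expected planted both-arm SNV changes per SGB.
#' @param snv_background_rate expected idiosyncratic per-host SNV changes per
#'   SGB (Poisson; low prevalence, removed by the 30% filter).
#' @param snv_prevalence_high fraction of a group's hosts sharing each
#'   planted SNV change (default 0.5).
#' @param snv_immunity_coupling effect (in indicator-delta sd units) added to
#'   one indicator's delta for carriers of one planted probiotic SNV.
#' @param zero_inflation per-entry probability that a non-planted feature is
#'   undetected in a sample.
#' @param sigma_feature,sigma_subject,sigma_within log-scale sd of feature
#'   means, subject effects, and within-subject noise.
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects_per_group = 45,
                          n_features = c(bacteria = 120, fungi = 40,
                                         "function" = 150, metabolite = 180),
                          n_indicators = 69,
                          indicator_split = c(cytokine = 34, cbc = 29,
                                              lymphocyte = 6),
                          convergence_factor = c(placebo = 0, probiotic = 0.3),
                          n_linked_pairs = 20,
                          n_shared_pairs = 5,
                          rho_link = 0.6,
                          n_drift_features = 8, drift_effect = 1.5,
                          n_shift_features = 8, shift_effect = 1.0,
                          n_sgbs = 20,
                          snv_group_rate = c(placebo = 3, probiotic = 1.2),
                          snv_shared_rate = 2,
                          snv_background_rate = 0.05,
                          snv_prevalence_high = 0.5,
                          snv_immunity_coupling = 1.5,
                          zero_inflation = 0.10,
                          sigma_feature = 1.2, sigma_subject = 0.8,
                          sigma_within = 0.3,
                          seed = 1) {
  cfg <- as.list(environment())
  if (n_subjects_per_group < 1) stop("need at least 1 subject per group")
  if (!all(LAYERS %in% names(n_features))) {
    stop("n_features must name all layers: ", paste(LAYERS, collapse = ", "))
  }
  if (!all(GROUPS %in% names(convergence_factor)) ||
      any(convergence_factor < 0) || any(convergence_factor > 1)) {
    stop("convergence_factor must be named per group and lie in [0, 1]")
  }
  if (abs(rho_link) >= 1) stop("rho_link must lie in (-1, 1)")
  rates <- c(snv_group_rate, snv_shared_rate, snv_background_rate)
  if (any(rates < 0)) stop("SNV rates must be >= 0")
  if (!all(GROUPS %in% names(snv_group_rate))) {
    stop("snv_group_rate must be named per group")
  }
  if (snv_prevalence_high <= 0 || snv_prevalence_high > 1) {
    stop("snv_prevalence_high must lie in (0, 1]")
  }
  if (n_linked_pairs + n_shared_pairs >
      min(n_features[["bacteria"]], n_indicators)) {
    stop("too many planted pairs for the bacteria layer / indicator panel")
  }
  # planted pairs occupy ~2.5% of composition mass each; keep the total well
  # below the simplex so renormalisation of the other features stays positive
  if ((n_linked_pairs + n_shared_pairs) * 0.025 > 0.8) {
    stop("planted pairs would occupy too much composition mass")
  }
  reserved <- n_drift_features + n_shift_features +
    n_linked_pairs + n_shared_pairs
  if (reserved > n_features[["bacteria"]]) {
    stop("planted feature blocks exceed the bacteria layer size")
  }
  if (sum(indicator_split) != n_indicators) {
    sc <- round(indicator_split * n_indicators / sum(indicator_split))
    sc[1] <- sc[1] + n_indicators - sum(sc)
    cfg$indicator_split <- sc
  }
  structure(cfg, class = "cohort_config")
}

.layer_prefix <- c(bacteria = "SGB", fungi = "FUN",
                   "function" = "PWY", metabolite = "MET")

# planted column blocks inside one layer: drift | shift | linked | shared
.plant_index <- function(cfg, layer) {
  nf <- cfg$n_features[[layer]]
  nd <- min(cfg$n_drift_features, nf)
  ns <- min(cfg$n_shift_features, nf - nd)
  out <- list(drift = seq_len(nd),
              shift = if (ns) nd + seq_len(ns) else integer(0),
              linked = integer(0), shared = integer(0))
  if (layer == "bacteria") {
    out$linked <- nd + ns + seq_len(cfg$n_linked_pairs)
    out$shared <- nd + ns + cfg$n_linked_pairs + seq_len(cfg$n_shared_pairs)
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' Produces the four omics layers, the immunity panel, per-sample SNV call
#' sets and a ground-truth record, deterministically from `config$seed`.
#' Mechanisms: (a) per-feature log-normal baselines with subject random
#' effects, relative-abundance layers closed to 1; (b) endline = baseline +
#' small common temporal drift + group noise, then shrunk toward the group
#' endline centroid by `convergence_factor`; (c) planted pairs get exact
#' bivariate-normal (feature delta, indicator delta) draws in composition
#' space; (d) SNV call sets evolve by planted high-prevalence gains/losses
#' (shared or arm-specific) plus Poisson background changes.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `config`,
#'   `metadata`, `tables` (named list of [feature_table()]), `immunity`,
#'   `snv` (named list of [snv_callset()]), `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_subjects_per_group

  subjects <- c(sprintf("PLA%03d", seq_len(n)), sprintf("PRO%03d", seq_len(n)))
  group_of <- stats::setNames(rep(GROUPS, each = n), subjects)
  md <- data.frame(
    sample_id = paste0(rep(subjects, each = 2), c("_B", "_E")),
    subject_id = rep(subjects, each = 2),
    group = rep(group_of, each = 2),
    timepoint = rep(TIMEPOINTS, times = 2 * n),
    stringsAsFactors = FALSE)
  md <- validate_metadata(md)

  pro <- subjects[group_of == "probiotic"]
  pla <- subjects[group_of == "placebo"]

  # ---- indicator panel scaffolding ----------------------------------------
  cats <- rep(names(cfg$indicator_split), times = cfg$indicator_split)
  ind_ids <- sprintf("%s_%02d", toupper(substr(cats, 1, 3)),
                     stats::ave(seq_along(cats), cats, FUN = seq_along))
  names(cats) <- ind_ids
  mu_ind <- stats::setNames(exp(stats::rnorm(cfg$n_indicators, 3, 1)), ind_ids)
  sd_ind <- 0.08 * mu_ind
  ind_base <- sweep(matrix(exp(stats::rnorm(2 * n * cfg$n_indicators, 0, 0.25)),
                           2 * n, cfg$n_indicators), 2, mu_ind, `*`)
  dimnames(ind_base) <- list(subjects, ind_ids)
  ind_delta <- sweep(matrix(stats::rnorm(2 * n * cfg$n_indicators),
                            2 * n, cfg$n_indicators), 2, sd_ind, `*`)
  dimnames(ind_delta) <- list(subjects, ind_ids)

  # indicator allocation: linked pairs then shared pairs then SNV coupling
  ind_linked <- ind_ids[seq_len(cfg$n_linked_pairs)]
  ind_shared <- ind_ids[cfg$n_linked_pairs + seq_len(cfg$n_shared_pairs)]
  ind_snv <- ind_ids[cfg$n_linked_pairs + cfg$n_shared_pairs + 1L]

  truth <- list(convergence_factor = cfg$convergence_factor,
                linked_pairs = NULL, shared_pairs = NULL,
                drift_features = NULL, shift_features = NULL)

  # ---- omics layers --------------------------------------------------------
  rbiv <- function(ns, sd1, sd2, rho) {
    z1 <- stats::rnorm(ns); z2 <- stats::rnorm(ns)
    cbind(sd1 * z1, sd2 * (rho * z1 + sqrt(1 - rho^2) * z2))
  }
  tables <- list()
  drift_rows <- list(); shift_rows <- list()
  linked_df <- NULL; shared_df <- NULL
  for (layer in LAYERS) {
    nf <- cfg$n_features[[layer]]
    fid <- sprintf("%s%03d", .layer_prefix[[layer]], seq_len(nf))
    pl <- .plant_index(cfg, layer)
    planted_cols <- c(pl$linked, pl$shared)

    sig_s <- if (layer == "metabolite") 0.12 else cfg$sigma_subject
    sig_w <- if (layer == "metabolite") 0.08 else cfg$sigma_within
    m_f <- stats::rnorm(nf, 0, cfg$sigma_feature)
    # a noisy block in the metabolite layer exercises the RSD filter
    noisy <- if (layer == "metabolite") {
      tail(seq_len(nf), max(1L, round(0.1 * nf)))
    } else integer(0)
    U <- matrix(stats::rnorm(2 * n * nf, 0, sig_s), 2 * n, nf)
    if (length(noisy)) {
      U[, noisy] <- matrix(stats::rnorm(2 * n * length(noisy), 0, 0.6),
                           2 * n, length(noisy))
    }
    # diffuse drift stays an order of magnitude below within-subject noise;
    # the interpretable time effect is carried by the planted drift features
    drift_all <- stats::rnorm(nf, 0, 0.01)
    sign_drift <- sample(c(-1, 1), length(pl$drift), replace = TRUE)
    sign_shift <- sample(c(-1, 1), length(pl$shift), replace = TRUE)
    drift_plant <- numeric(nf)
    drift_plant[pl$drift] <- sign_drift * cfg$drift_effect * cfg$sigma_within
    shift_plant <- numeric(nf)
    shift_plant[pl$shift] <- sign_shift * cfg$shift_effect * cfg$sigma_within

    Lb <- sweep(U, 2, m_f, `+`) +
      matrix(stats::rnorm(2 * n * nf, 0, sig_w), 2 * n, nf)
    Le <- sweep(U, 2, m_f + drift_all + drift_plant, `+`) +
      matrix(stats::rnorm(2 * n * nf, 0, sig_w), 2 * n, nf)
    is_pro <- group_of[subjects] == "probiotic"
    Le[is_pro, ] <- sweep(Le[is_pro, , drop = FALSE], 2, shift_plant, `+`)

    Ab <- exp(Lb); Ae <- exp(Le)
    if (cfg$zero_inflation > 0) {
      zb <- matrix(stats::runif(2 * n * nf) < cfg$zero_inflation, 2 * n, nf)
      ze <- matrix(stats::runif(2 * n * nf) < cfg$zero_inflation, 2 * n, nf)
      keep_cols <- c(pl$drift, pl$shift, planted_cols)
      zb[, keep_cols] <- FALSE; ze[, keep_cols] <- FALSE
      Ab[zb] <- 0; Ae[ze] <- 0
      # no sample may end up all-zero: restore its most abundant feature
      fix <- function(A, Aorig) {
        dead <- which(rowSums(A) == 0)
        for (i in dead) {
          j <- which.max(Aorig[i, ])
          A[i, j] <- Aorig[i, j]
        }
        A
      }
      Ab <- fix(Ab, exp(Lb)); Ae <- fix(Ae, exp(Le))
    }
    dimnames(Ab) <- dimnames(Ae) <- list(subjects, fid)

    if (layer %in% REL_LAYERS) {
      Pb <- Ab / rowSums(Ab)
      Pe <- Ae / rowSums(Ae)
      # centroid shrinkage toward the group endline centroid
      for (g in GROUPS) {
        k <- cfg$convergence_factor[[g]]
        if (k > 0) {
          rows <- group_of[subjects] == g
          cent <- colMeans(Pe[rows, , drop = FALSE])
          Pe[rows, ] <- (1 - k) * Pe[rows, , drop = FALSE] +
            k * matrix(cent, sum(rows), nf, byrow = TRUE)
        }
      }
      if (length(planted_cols)) {
        # exact planted proportions: tight baselines, additive endline deltas
        base_p <- matrix(0.02 * exp(stats::rnorm(2 * n * length(planted_cols),
                                                 0, 0.1)),
                         2 * n, length(planted_cols))
        end_p <- base_p
        for (jj in seq_along(planted_cols)) {
          col <- planted_cols[jj]
          pair_kind <- if (col %in% pl$linked) "linked" else "shared"
          target_groups <- if (pair_kind == "linked") "probiotic" else GROUPS
          ind_id <- if (pair_kind == "linked") {
            ind_linked[match(col, pl$linked)]
          } else {
            ind_shared[match(col, pl$shared)]
          }
          dfi <- numeric(2 * n)
          for (g in GROUPS) {
            rows <- which(group_of[subjects] == g)
            if (g %in% target_groups) {
              bv <- rbiv(length(rows), 0.004, sd_ind[[ind_id]], cfg$rho_link)
              dfi[rows] <- bv[, 1]
              ind_delta[rows, ind_id] <- bv[, 2]
            } else {
              dfi[rows] <- stats::rnorm(length(rows), 0, 0.004)
            }
          }
          end_p[, jj] <- pmax(base_p[, jj] + dfi, 1e-6)
          rec <- data.frame(layer = layer, feature = fid[col],
                            indicator = ind_id,
                            sign = if (cfg$rho_link >= 0) "+" else "-",
                            stringsAsFactors = FALSE)
          if (pair_kind == "linked") {
            linked_df <- rbind(linked_df, rec)
          } else {
            shared_df <- rbind(shared_df, rec)
          }
        }
        renorm <- function(P, cols, repl) {
          other <- setdiff(seq_len(ncol(P)), cols)
          scale <- (1 - rowSums(repl)) / rowSums(P[, other, drop = FALSE])
          P[, other] <- P[, other, drop = FALSE] * scale
          P[, cols] <- repl
          P
        }
        Pb <- renorm(Pb, planted_cols, base_p)
        Pe <- renorm(Pe, planted_cols, end_p)
      }
      Vb <- Pb; Ve <- Pe
    } else {
      scale_met <- 2e4
      Vb <- Ab * scale_met; Ve <- Ae * scale_met
      for (g in GROUPS) {
        k <- cfg$convergence_factor[[g]]
        if (k > 0) {
          rows <- group_of[subjects] == g
          cent <- colMeans(Ve[rows, , drop = FALSE])
          Ve[rows, ] <- (1 - k) * Ve[rows, , drop = FALSE] +
            k * matrix(cent, sum(rows), nf, byrow = TRUE)
        }
      }
    }

    vals <- matrix(0, 4 * n, nf,
                   dimnames = list(md$sample_id, fid))
    vals[paste0(subjects, "_B"), ] <- Vb
    vals[paste0(subjects, "_E"), ] <- Ve
    tables[[layer]] <- feature_table(vals, md, layer)
    if (length(pl$drift)) {
      drift_rows[[layer]] <- data.frame(
        layer = layer, feature = fid[pl$drift],
        sign = ifelse(sign_drift > 0, "+", "-"), stringsAsFactors = FALSE)
    }
    if (length(pl$shift)) {
      shift_rows[[layer]] <- data.frame(
        layer = layer, feature = fid[pl$shift],
        sign = ifelse(sign_shift > 0, "+", "-"), stringsAsFactors = FALSE)
    }
  }
  truth$linked_pairs <- linked_df
  truth$shared_pairs <- shared_df
  truth$drift_features <- do.call(rbind, unname(drift_rows))
  truth$shift_features <- do.call(rbind, unname(shift_rows))

  # ---- SNV catalogue and per-host call sets -------------------------------
  sgbs <- sprintf("SGB%03d", seq_len(cfg$n_sgbs))
  contigs <- stats::setNames(paste0(sgbs, "_c1"), sgbs)
  species <- stats::setNames(sprintf("Synthetica organismi_%03d",
                                     seq_len(cfg$n_sgbs)), sgbs)
  n_uni <- round(cfg$snv_group_rate * cfg$n_sgbs)
  n_sh <- round(cfg$snv_shared_rate * cfg$n_sgbs)
  n_core <- 5 * cfg$n_sgbs
  n_bg_pool <- 40 * cfg$n_sgbs
  n_keys <- sum(n_uni) + n_sh + n_core + n_bg_pool

  key_sgb <- sample(sgbs, n_keys, replace = TRUE)
  key_pos <- integer(n_keys)
  for (s in sgbs) {
    ii <- which(key_sgb == s)
    key_pos[ii] <- sample.int(1e6, length(ii))
  }
  bases <- c("A", "C", "G", "T")
  key_ref <- sample(bases, n_keys, replace = TRUE)
  key_alt <- vapply(key_ref, function(r) sample(setdiff(bases, r), 1), "")
  keys <- snv_key(key_sgb, contigs[key_sgb], key_pos, key_ref, key_alt)

  off <- 0L
  take <- function(k) {
    out <- keys[off + seq_len(k)]
    off <<- off + k
    out
  }
  uni_keys <- list(placebo = take(n_uni[["placebo"]]),
                   probiotic = take(n_uni[["probiotic"]]))
  sh_keys <- take(n_sh)
  core_keys <- take(n_core)
  bg_pool <- take(n_bg_pool)

  base_calls <- stats::setNames(vector("list", 2 * n), subjects)
  end_calls <- stats::setNames(vector("list", 2 * n), subjects)
  for (s in subjects) {
    core <- core_keys[stats::runif(n_core) < 0.8]
    base_calls[[s]] <- core
    end_calls[[s]] <- core
  }
  n_carry <- ceiling(cfg$snv_prevalence_high * n)
  plant_change <- function(key, hosts, gained) {
    for (s in hosts) {
      if (gained) {
        end_calls[[s]] <<- c(end_calls[[s]], key)
      } else {
        base_calls[[s]] <<- c(base_calls[[s]], key)
      }
    }
  }
  carriers <- list(placebo = list(), probiotic = list())
  for (g in GROUPS) {
    gs <- subjects[group_of == g]
    for (i in seq_along(uni_keys[[g]])) {
      hosts <- sample(gs, n_carry)
      carriers[[g]][[uni_keys[[g]][i]]] <- hosts
      plant_change(uni_keys[[g]][i], hosts, gained = (i %% 2 == 1))
    }
  }
  sh_carriers <- list()
  for (i in seq_along(sh_keys)) {
    hosts <- c(sample(pla, n_carry), sample(pro, n_carry))
    sh_carriers[[sh_keys[i]]] <- hosts
    plant_change(sh_keys[i], hosts, gained = (i %% 2 == 1))
  }
  lam <- cfg$snv_background_rate * cfg$n_sgbs
  for (s in subjects) {
    k <- stats::rpois(1, lam)
    if (k > 0) {
      bk <- sample(bg_pool, min(k, length(bg_pool)))
      gained <- stats::runif(length(bk)) < 0.5
      base_calls[[s]] <- c(base_calls[[s]], bk[!gained])
      end_calls[[s]] <- c(end_calls[[s]], bk[gained])
    }
  }

  # SNV-immunity coupling: carriers of the first planted probiotic SNV get a
  # shifted delta on a dedicated indicator
  snv_link <- NULL
  if (cfg$snv_immunity_coupling > 0 && length(uni_keys$probiotic)) {
    key <- uni_keys$probiotic[1]
    hosts <- carriers$probiotic[[key]]
    ind_delta[hosts, ind_snv] <- ind_delta[hosts, ind_snv] +
      cfg$snv_immunity_coupling * sd_ind[[ind_snv]]
    snv_link <- data.frame(key = key, indicator = ind_snv,
                           n_carriers = length(hosts),
                           stringsAsFactors = FALSE)
  }

  # ---- assemble immunity panel --------------------------------------------
  ind_end <- pmax(ind_base + ind_delta,
                  matrix(0.01 * mu_ind, 2 * n, cfg$n_indicators, byrow = TRUE))
  ind_vals <- matrix(0, 4 * n, cfg$n_indicators,
                     dimnames = list(md$sample_id, ind_ids))
  ind_vals[paste0(subjects, "_B"), ] <- ind_base
  ind_vals[paste0(subjects, "_E"), ] <- ind_end
  immunity <- immunity_panel(ind_vals, md, cats)

  snv <- list()
  for (s in subjects) {
    for (tp in TIMEPOINTS) {
      sid <- paste0(s, if (tp == "baseline") "_B" else "_E")
      calls <- if (tp == "baseline") base_calls[[s]] else end_calls[[s]]
      snv[[sid]] <- snv_callset(md[md$sample_id == sid, , drop = FALSE],
                                calls)
    }
  }

  truth$unique_snvs <- uni_keys
  truth$shared_snvs <- sh_keys
  truth$snv_immunity <- snv_link
  truth$sgb_species <- species
  truth$contig_map <- stats::setNames(sgbs, unname(contigs))

  structure(list(config = cfg, metadata = md, tables = tables,
                 immunity = immunity, snv = snv, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects/arm, %d samples, seed=%d\n",
              x$config$n_subjects_per_group, nrow(x$metadata),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Emits exactly the formats the I/O layer consumes: per-layer feature TSVs,
#' metadata TSV, immunity TSV, one VCF per sample, contig->SGB and
#' SGB->species maps, and the ground truth as TSVs.  Two runs with the same
#' seed produce byte-identical trees.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("unwritable directory: ", dir)
  write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"))
  for (layer in names(cohort$tables)) {
    write_feature_table(cohort$tables[[layer]],
                        file.path(dir, paste0("features_", layer, ".tsv")))
  }
  write_immunity_panel(cohort$immunity, file.path(dir, "immunity.tsv"))
  vdir <- file.path(dir, "vcf")
  dir.create(vdir, showWarnings = FALSE)
  for (sid in names(cohort$snv)) {
    write_vcf_calls(cohort$snv[[sid]], file.path(vdir, paste0(sid, ".vcf")))
  }
  cm <- cohort$truth$contig_map
  write_tsv(data.frame(contig = names(cm), sgb_id = unname(cm),
                       stringsAsFactors = FALSE),
            file.path(dir, "contig_map.tsv"))
  sp <- cohort$truth$sgb_species
  write_tsv(data.frame(sgb_id = names(sp), species = unname(sp),
                       stringsAsFactors = FALSE),
            file.path(dir, "sgb_species.tsv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in c("linked_pairs", "shared_pairs", "drift_features",
               "shift_features", "snv_immunity")) {
    df <- cohort$truth[[nm]]
    if (!is.null(df)) write_tsv(df, file.path(tdir, paste0(nm, ".tsv")))
  }
  snv_truth <- rbind(
    data.frame(key = cohort$truth$unique_snvs$placebo, set = "unique_placebo",
               stringsAsFactors = FALSE),
    data.frame(key = cohort$truth$unique_snvs$probiotic,
               set = "unique_probiotic", stringsAsFactors = FALSE),
    data.frame(key = cohort$truth$shared_snvs, set = "shared",
               stringsAsFactors = FALSE))
  write_tsv(snv_truth, file.path(tdir, "snv_truth.tsv"))
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param vcf_min_quality,vcf_min_depth thresholds forwarded to
#'   [read_vcf_calls()].
#' @return list with `metadata`, `tables`, `immunity`, `snv`, `contig_map`,
#'   `sgb_species`.
#' @export
read_cohort <- function(dir, vcf_min_quality = 60, vcf_min_depth = 100) {
  md <- read_metadata(file.path(dir, "metadata.tsv"))
  tables <- list()
  for (layer in LAYERS) {
    p <- file.path(dir, paste0("features_", layer, ".tsv"))
    if (file.exists(p)) tables[[layer]] <- read_feature_table(p, layer, md)
  }
  immunity <- read_immunity_panel(file.path(dir, "immunity.tsv"), md)
  cm <- read_contig_map(file.path(dir, "contig_map.tsv"))
  sp_path <- file.path(dir, "sgb_species.tsv")
  species <- if (file.exists(sp_path)) read_sgb_species_map(sp_path) else NULL
  snv <- list()
  vdir <- file.path(dir, "vcf")
  if (dir.exists(vdir)) {
    for (f in sort(list.files(vdir, pattern = "\\.vcf$", full.names = TRUE))) {
      sid <- sub("\\.vcf$", "", basename(f))
      snv[[sid]] <- read_vcf_calls(f, md[md$sample_id == sid, , drop = FALSE],
                                   cm, vcf_min_quality, vcf_min_depth)
    }
  }
  list(metadata = md, tables = tables, immunity = immunity, snv = snv,
       contig_map = cm, sgb_species = species)
}
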