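#' @keywords internal
"_PACKAGE"

GROUPS <- c("placebo", "probiotic")
TIMEPOINTS <- c("baseline", "endline")
LAYERS <- c("bacteria", "fungi", "function", "metabolite")
REL_LAYERS <- c("bacteria", "fungi", "function")
CATEGORIES <- c("cytokine", "cbc", "lymphocyte")

# ---- logging ---------------------------------------------------------------

#' Emit a pipeline log line
#'
#' Every filtering step in the package reports counts in/out through this
#' function.  Lines are emitted with [message()] when
#' `options(deltaomics.verbose = TRUE)` (the CLI sets this), and are silent
#' otherwise so programmatic use stays quiet.
#'
#' @param fmt `sprintf` format string.
#' @param ... values interpolated into `fmt`.
#' @return invisibly, the formatted line.
#' @export
do_log <- function(fmt, ...) {
  line <- sprintf(fmt, ...)
  if (isTRUE(getOption("deltaomics.verbose", FALSE))) {
    message("[deltaomics] ", line)
  }
  invisible(line)
}

# ---- sample metadata -------------------------------------------------------

#' Validate study sample metadata
#'
#' Metadata maps each sample id to its subject, arm and timepoint.  A subject
#' must belong to exactly one arm across all records and each
#' (subject, timepoint) pair must be unique.
#'
#' @param metadata data.frame with columns `sample_id`, `subject_id`, `group`
#'   (`"placebo"`/`"probiotic"`), `timepoint` (`"baseline"`/`"endline"`).
#' @return the validated data.frame (character columns, row names stripped).
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "subject_id", "group", "timepoint")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  md <- as.data.frame(lapply(metadata[need], as.character),
                      stringsAsFactors = FALSE)
  rownames(md) <- NULL
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  bad_g <- setdiff(unique(md$group), GROUPS)
  if (length(bad_g)) stop("unknown group token: ", paste(bad_g, collapse = ", "))
  bad_t <- setdiff(unique(md$timepoint), TIMEPOINTS)
  if (length(bad_t)) stop("unknown timepoint token: ", paste(bad_t, collapse = ", "))
  key <- paste(md$subject_id, md$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, timepoint) pair: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  ngrp <- tapply(md$group, md$subject_id, function(g) length(unique(g)))
  if (any(ngrp > 1)) {
    stop("subject assigned to more than one group: ",
         paste(names(ngrp)[ngrp > 1], collapse = ", "))
  }
  md
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `group`,
#'   `timepoint`; lines starting with `#` are ignored.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  validate_metadata(read_tsv(path))
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE, ...)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
}

# subjects present at both timepoints
paired_subjects <- function(samples, group = NULL) {
  md <- samples
  if (!is.null(group)) md <- md[md$group %in% group, , drop = FALSE]
  tab <- table(md$subject_id, md$timepoint)
  if (!all(TIMEPOINTS %in% colnames(tab))) return(character(0))
  sort(rownames(tab)[tab[, "baseline"] > 0 & tab[, "endline"] > 0])
}

# ---- feature table ---------------------------------------------------------

#' Construct a feature table for one omics layer
#'
#' A samples x features matrix of non-negative values plus sample metadata.
#' Relative-abundance layers (`bacteria`, `fungi`, `function`) must have
#' per-sample row sums in (0, 1 + 1e-9]; the `metabolite` layer carries raw
#' peak intensities.
#'
#' @param values numeric matrix, rows = samples, columns = features.
#' @param samples metadata data.frame (one row per value-matrix row, matched
#'   by `sample_id` against `rownames(values)`).
#' @param layer one of `"bacteria"`, `"fungi"`, `"function"`, `"metabolite"`.
#' @return object of class `feature_table` with fields `layer`, `samples`,
#'   `features`, `values`.
#' @export
feature_table <- function(values, samples, layer) {
  layer <- match.arg(layer, LAYERS)
  samples <- validate_metadata(samples)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  if (is.null(colnames(values))) {
    stop("feature table values must have feature ids as column names")
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  extra <- setdiff(rownames(values), samples$sample_id)
  if (length(extra)) {
    stop("sample(s) missing from metadata: ", paste(extra, collapse = ", "))
  }
  missing_rows <- setdiff(samples$sample_id, rownames(values))
  if (length(missing_rows)) {
    stop("metadata sample(s) absent from table: ",
         paste(missing_rows, collapse = ", "))
  }
  values <- values[samples$sample_id, , drop = FALSE]
  if (anyNA(values)) stop("missing value in feature table")
  if (any(values < 0)) stop("negative abundance in feature table")
  if (layer %in% REL_LAYERS) {
    rs <- rowSums(values)
    if (any(rs <= 0)) stop("all-zero sample in relative-abundance layer")
    if (any(rs > 1 + 1e-9)) {
      stop("relative-abundance row sum exceeds 1: max = ", format(max(rs)))
    }
  }
  structure(list(layer = layer, samples = samples,
                 features = colnames(values), values = values),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> layer=%s  %d samples x %d features\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read one omics layer from TSV
#'
#' The TSV has a header row of sample ids and a first column of feature ids.
#' Every sample column must be present in the metadata; unknown samples are an
#' error (strict join), never a silent drop.
#'
#' @param path feature TSV (features x samples on disk).
#' @param layer layer name, see [feature_table()].
#' @param metadata metadata data.frame or path to a metadata TSV.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, layer, metadata) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  metadata <- validate_metadata(metadata)
  df <- read_tsv(path)
  if (ncol(df) < 2) stop("malformed feature TSV (need id column + samples): ", path)
  fid <- as.character(df[[1]])
  if (anyDuplicated(fid)) {
    stop("duplicate feature id: ", paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("malformed feature TSV (non-numeric values): ", path)
  sample_ids <- colnames(df)[-1]
  unknown <- setdiff(sample_ids, metadata$sample_id)
  if (length(unknown)) {
    stop("sample(s) missing from metadata: ", paste(unknown, collapse = ", "))
  }
  md <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  vals <- t(m)
  dimnames(vals) <- list(sample_ids, fid)
  feature_table(vals, md, layer)
}

#' Write one omics layer to TSV (features x samples)
#'
#' @param table a [feature_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature_id = table$features,
                   t(table$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# ---- immunity panel --------------------------------------------------------

#' Construct an immunity-indicator panel
#'
#' Blood immune-function test results: a samples x indicators matrix of
#' positive values plus an indicator -> category map
#' (cytokine / cbc / lymphocyte).  The study design expects 69 indicators
#' (34 cytokines, 29 CBC, 6 lymphocyte) but any count is accepted.
#'
#' @param values numeric matrix, rows = samples, columns = indicators.
#' @param samples sample metadata data.frame.
#' @param categories named character vector indicator_id -> category.
#' @return object of class `immunity_panel`.
#' @export
immunity_panel <- function(values, samples, categories) {
  samples <- validate_metadata(samples)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("immunity values need indicator ids")
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  values <- values[samples$sample_id, , drop = FALSE]
  miss <- setdiff(colnames(values), names(categories))
  if (length(miss)) {
    stop("indicator(s) missing from category map: ", paste(miss, collapse = ", "))
  }
  categories <- categories[colnames(values)]
  bad <- setdiff(unique(categories), CATEGORIES)
  if (length(bad)) stop("unknown indicator category: ", paste(bad, collapse = ", "))
  if (anyNA(values) || any(values <= 0)) {
    stop("immunity panel values must be positive")
  }
  structure(list(samples = samples, indicators = colnames(values),
                 categories = categories, values = values),
            class = "immunity_panel")
}

#' @export
print.immunity_panel <- function(x, ...) {
  cat(sprintf("<immunity_panel> %d samples x %d indicators (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$categories)),
                            as.integer(table(x$categories))), collapse = ", ")))
  invisible(x)
}

#' Read an immunity panel from TSV
#'
#' Layout: column 1 `indicator_id`, column 2 `category`, remaining columns one
#' per sample id.
#'
#' @inheritParams read_feature_table
#' @return an [immunity_panel()].
#' @export
read_immunity_panel <- function(path, metadata) {
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  df <- read_tsv(path)
  if (ncol(df) < 3 || names(df)[1] != "indicator_id" || names(df)[2] != "category") {
    stop("malformed immunity TSV (expect indicator_id, category, samples...)")
  }
  cats <- stats::setNames(as.character(df$category), df$indicator_id)
  sample_ids <- names(df)[-(1:2)]
  unknown <- setdiff(sample_ids, metadata$sample_id)
  if (length(unknown)) {
    stop("sample(s) missing from metadata: ", paste(unknown, collapse = ", "))
  }
  vals <- t(as.matrix(df[, -(1:2), drop = FALSE]))
  dimnames(vals) <- list(sample_ids, df$indicator_id)
  md <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  immunity_panel(vals, md, cats)
}

#' Write an immunity panel to TSV
#'
#' @param panel an [immunity_panel()].
#' @param path output path.
#' @export
write_immunity_panel <- function(panel, path) {
  df <- data.frame(indicator_id = panel$indicators,
                   category = unname(panel$categories[panel$indicators]),
                   t(panel$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# ---- SNV keys and call sets ------------------------------------------------

#' Build canonical SNV key strings
#'
#' An SNV is identified by (SGB, contig, 1-based position, REF base, ALT
#' base); alleles are part of the identity, so a second ALT at the same
#' position is a distinct SNV.
#'
#' @param sgb_id,contig,pos,ref,alt vectors of equal length.
#' @return character vector `"sgb|contig|pos|REF>ALT"`.
#' @export
snv_key <- function(sgb_id, contig, pos, ref, alt) {
  pos <- as.integer(pos)
  if (any(pos < 1)) stop("SNV position must be >= 1")
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("SNV alleles must be single upper-case bases")
  if (any(ref == alt)) stop("SNV ref and alt alleles must differ")
  sprintf("%s|%s|%d|%s>%s", sgb_id, contig, pos, ref, alt)
}

snv_key_df <- function(keys) {
  if (!length(keys)) {
    return(data.frame(sgb_id = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  al <- strsplit(vapply(parts, `[[`, "", 4L), ">", fixed = TRUE)
  data.frame(sgb_id = vapply(parts, `[[`, "", 1L),
             contig = vapply(parts, `[[`, "", 2L),
             pos = as.integer(vapply(parts, `[[`, "", 3L)),
             ref = vapply(al, `[[`, "", 1L),
             alt = vapply(al, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Construct an SNV call set for one sample
#'
#' @param sample one-row metadata data.frame identifying the sample.
#' @param calls character vector of canonical [snv_key()] strings (set
#'   semantics: deduplicated and sorted).
#' @param min_quality,min_depth the filters that produced the set.
#' @return object of class `snv_callset`.
#' @export
snv_callset <- function(sample, calls, min_quality = 60, min_depth = 100) {
  sample <- validate_metadata(sample)
  if (nrow(sample) != 1L) stop("snv_callset expects exactly one sample row")
  if (min_quality < 0 || min_depth < 0) stop("filters must be non-negative")
  calls <- sort(unique(as.character(calls)))
  structure(list(sample = sample, calls = calls,
                 filters = list(min_quality = min_quality,
                                min_depth = min_depth)),
            class = "snv_callset")
}

#' @export
print.snv_callset <- function(x, ...) {
  cat(sprintf("<snv_callset> %s (%s/%s): %d calls [QUAL>=%g, DP>=%g]\n",
              x$sample$sample_id, x$sample$group, x$sample$timepoint,
              length(x$calls), x$filters$min_quality, x$filters$min_depth))
  invisible(x)
}

#' Read a contig -> SGB map from two-column TSV
#'
#' @param path TSV with columns `contig`, `sgb_id`.
#' @return named character vector contig -> sgb_id.
#' @export
read_contig_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("contig", "sgb_id") %in% names(df))) {
    stop("contig map needs columns contig, sgb_id")
  }
  stats::setNames(as.character(df$sgb_id), as.character(df$contig))
}

#' Read an SGB -> species annotation map
#'
#' @param path TSV with columns `sgb_id`, `species`.
#' @return named character vector sgb_id -> species.
#' @export
read_sgb_species_map <- function(path) {
  df <- read_tsv(path)
  if (!all(c("sgb_id", "species") %in% names(df))) {
    stop("species map needs columns sgb_id, species")
  }
  stats::setNames(as.character(df$species), as.character(df$sgb_id))
}

#' Read quality/depth-filtered SNV calls from a VCF
#'
#' Parses the minimal VCF v4.2 subset used for metagenome SNV profiling and
#' keeps biallelic single-base substitutions with `QUAL >= min_quality` and
#' depth `>= min_depth`.  Multi-allelic records are split and each ALT allele
#' is filtered independently; indels and multi-nucleotide records are
#' excluded.  Depth is taken from FORMAT/DP of the first sample when present,
#' else INFO/DP; records with no depth are skipped with a logged count.
#'
#' @param path uncompressed VCF file.
#' @param sample one-row metadata data.frame for the sample.
#' @param contig_map named character vector contig -> sgb_id; a record whose
#'   contig has no mapping is an error naming the contig.
#' @param min_quality minimum QUAL, inclusive (default 60).
#' @param min_depth minimum read depth, inclusive (default 100).
#' @return an [snv_callset()].
#' @export
read_vcf_calls <- function(path, sample, contig_map,
                           min_quality = 60, min_depth = 100) {
  if (!file.exists(path)) stop("unreadable VCF: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#")]
  n_in <- length(body)
  keys <- character(0)
  n_no_dp <- 0L
  if (n_in) {
    f <- strsplit(body, "\t", fixed = TRUE)
    nf <- vapply(f, length, 1L)
    if (any(nf < 8L)) stop("malformed VCF record (fewer than 8 fields) in ", path)
    chrom <- vapply(f, `[[`, "", 1L)
    unmapped <- setdiff(unique(chrom), names(contig_map))
    if (length(unmapped)) {
      stop("contig(s) with no SGB mapping: ", paste(unmapped, collapse = ", "))
    }
    pos <- as.integer(vapply(f, `[[`, "", 2L))
    ref <- vapply(f, `[[`, "", 4L)
    alt <- vapply(f, `[[`, "", 5L)
    qual <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 6L)))
    info <- vapply(f, `[[`, "", 8L)
    dp <- rep(NA_real_, n_in)
    # FORMAT/DP (first sample column) preferred, INFO/DP fallback
    has_fmt <- nf >= 10L
    if (any(has_fmt)) {
      fmt <- ifelse(has_fmt, vapply(f, function(x) x[min(9L, length(x))], ""), "")
      smp <- ifelse(has_fmt, vapply(f, function(x) x[min(10L, length(x))], ""), "")
      for (i in which(has_fmt)) {
        kk <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
        j <- match("DP", kk)
        if (!is.na(j)) {
          vv <- strsplit(smp[i], ":", fixed = TRUE)[[1]]
          if (j <= length(vv)) dp[i] <- suppressWarnings(as.numeric(vv[j]))
        }
      }
    }
    need_info <- is.na(dp)
    if (any(need_info)) {
      has_dp <- grepl("(^|;)DP=[0-9]+", info)
      for (i in which(need_info & has_dp)) {
        dp[i] <- as.numeric(sub(".*?(^|;)DP=([0-9]+).*", "\\2", info[i]))
      }
    }
    n_no_dp <- sum(is.na(dp))
    keep_rec <- !is.na(dp) & !is.na(qual) & qual >= min_quality & dp >= min_depth
    for (i in which(keep_rec)) {
      if (!ref[i] %in% c("A", "C", "G", "T")) next
      for (a in strsplit(alt[i], ",", fixed = TRUE)[[1]]) {
        if (a %in% c("A", "C", "G", "T") && a != ref[i]) {
          keys <- c(keys, snv_key(contig_map[[chrom[i]]], chrom[i], pos[i],
                                  ref[i], a))
        }
      }
    }
  }
  do_log("read_vcf_calls(%s): %d records in, %d calls kept, %d skipped (no DP)",
         basename(path), n_in, length(keys), n_no_dp)
  snv_callset(sample, keys, min_quality, min_depth)
}

#' Write an SNV call set as a minimal VCF v4.2
#'
#' Emits one data line per call with `QUAL = 100`, `FILTER = PASS` and
#' `INFO = DP=200` (both above the default read thresholds), positions sorted
#' within contig, so that `read_vcf_calls(write_vcf_calls(s))` reproduces the
#' set whenever the read thresholds are satisfied.
#'
#' @param callset an [snv_callset()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf_calls <- function(callset, path) {
  df <- snv_key_df(callset$calls)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=deltaomics",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    sprintf("##contig=<ID=%s>", sort(unique(df$contig))),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- header
  if (nrow(df)) {
    o <- order(df$contig, df$pos, df$ref, df$alt)
    df <- df[o, , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\tDP=200",
                              df$contig, df$pos, df$ref, df$alt))
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("unwritable path: ", path)
  invisible(path)
}

# ---- config ----------------------------------------------------------------

#' Default analysis configuration
#'
#' Nested list holding every threshold used by the pipeline; any entry can be
#' overridden by a JSON config file ([read_config()]) or a CLI flag.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    vcf = list(min_quality = 60, min_depth = 100),
    snv = list(prevalence = 0.30, direction_scope = "either",
               pooled_prevalence = FALSE, alpha = 0.05),
    qc = list(min_intensity = 1000, min_prevalence = 0.20, max_rsd = 0.20,
              rsd_scope = "pooled"),
    clr = list(pseudocount_factor = 0.65),
    differential = list(alpha = 0.05, min_pairs = 6,
                        strict_probiotic_only = FALSE, fdr = FALSE),
    indirect = list(alpha = 0.05, fdr = FALSE,
                    spearman_threshold_is_p_value = TRUE,
                    union_proportion = FALSE),
    diversity = list(n_permutations = 999, seed = 20260911,
                     standardize_deltas = FALSE)
  )
}

#' Read a JSON configuration file, merged over the defaults
#'
#' @param path JSON file with any subset of the [default_config()] tree.
#' @return nested named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  merge_list <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_list(base[[k]], over[[k]])
      } else over[[k]]
    }
    base
  }
  merge_list(cfg, user)
}
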