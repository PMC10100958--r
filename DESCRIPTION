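Package: deltaomics
Title: Paired Two-Arm Multiomics Intervention Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R: person("Open", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for placebo-controlled, two-timepoint
    (baseline/endline) multiomics intervention studies of the gut microbiome.
    Provides alpha diversity (Shannon), Bray-Curtis beta diversity and
    within-group convergence testing, a from-scratch permutation PERMANOVA,
    metabolomics quality control with centred log-ratio preprocessing, paired
    differential-change testing with cross-group time-effect subtraction,
    delta-correlation ("indirect influence") association screening against an
    immunity-indicator panel, and a gut metagenome SNV treatment-attribution
    procedure based on within-host temporal changes, cohort prevalence
    filtering and placebo subtraction. A deterministic synthetic-cohort
    generator with planted, recorded effects supplies ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
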