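# deltaomics

Statistical toolkit for placebo-controlled, two-timepoint multiomics
intervention studies of the gut microbiome — the design in which each subject
is sampled at **baseline** and **endline**, one arm receives a probiotic and
the other a placebo, and the question is what the intervention did to the
microbiome (bacterial and fungal composition, microbial function), the
metabolome, and a panel of blood immunity indicators.

The package is aimed at microbiome statisticians and bioinformaticians who
have per-sample feature tables (taxa / functions / metabolites), an
immunity-indicator panel, and per-sample VCFs of metagenome SNVs called
against species-level genome bins (SGBs), and who want the full
treatment-attribution analysis rather than plain cross-sectional testing.

## What it computes

Everything is built around *per-subject change* (Δ = endline − baseline) and
*placebo subtraction* — signals that appear identically in both arms are
attributed to time, not treatment.

- **Diversity and convergence.** Shannon index
  `H = −Σ pᵢ ln pᵢ`; Bray–Curtis dissimilarity
  `BC(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`; a from-scratch one-way permutation
  PERMANOVA on distances (Anderson's pseudo-F,
  `F = (SS_B/(a−1)) / (SS_W/(N−a))`, p by label permutation with an exact
  enumeration mode); within-group BC dissimilarity lists and the
  rank-sum / signed-rank convergence comparisons.
- **Paired differential analysis.** Metabolite QC (intensity ≥ 1000 in
  ≥ 20 % of each arm, RSD ≤ 20 %), centred log-ratio transform with
  multiplicative zero replacement, Wilcoxon signed-rank on per-subject
  changes in each arm (exact tie-aware null up to n = 25), then
  **time-effect subtraction**: features significant in the *same direction in
  both arms* are classified `time_effect` and discarded; the rest of the
  significant features are `treatment_differential` (the "direct influence"),
  summarised as a count ratio and a summed relative-abundance proportion.
- **Indirect influence.** All feature × indicator Spearman correlations of
  per-subject deltas, separately per arm; edges with p < 0.05 are kept, edges
  with identical (feature, indicator, sign) in both arms are removed as time
  effects; implicated features are counted and their endline proportions
  summed.
- **SNV treatment attribution.** Per-host temporal SNV changes
  (gained/lost between timepoints, from quality-filtered VCFs:
  QUAL ≥ 60, depth ≥ 100, single-base substitutions only), a ≥ 30 %
  within-arm prevalence filter, Venn subtraction of the arms' candidate sets
  (the intersection is a time effect), per-species categorisation with dense
  ranks, and association of group-unique SNVs with immunity-indicator
  changes.
- **Synthetic cohorts.** `generate_cohort()` builds a full two-arm cohort
  (log-normal abundances with subject effects, centroid-shrinkage
  convergence, planted delta-correlations with a target ρ, planted SNV
  gain/loss processes) and records the ground truth, so every pipeline stage
  can be validated against known plants.

## Worked example

```r
library(deltaomics)
cfg <- cohort_config(n_subjects_per_group = 45, seed = 20230313)
co  <- generate_cohort(cfg)           # 45/arm x 2 timepoints = 180 samples
write_cohort(co, "cohort")
res <- run_pipeline("cohort", "results")

res$convergence$signed_rank[, c("layer", "group", "p_value", "direction")]
#>       layer     group   p_value direction
#>    bacteria   placebo 6.43e-104        up
#>    bacteria probiotic 1.44e-123      down     <- planted convergence (kappa = 0.3)
#>    ...

res$direct[res$direct$layer == "bacteria", ]
#>     layer n_differential n_total count_ratio proportion
#>  bacteria             17     120       0.142     0.0842

res$indirect_summary[res$indirect_summary$layer == "bacteria", ]
#>     layer n_implicated n_total count_ratio proportion
#>  bacteria          115     120       0.958       0.96

res$snv$attribution
#> <attribution_result> unique: probiotic 24, placebo 60; shared 40
```

Reading the numbers: the probiotic arm's within-group Bray–Curtis
dissimilarity drops (the planted centroid shrinkage is detected as
convergence); the *direct* influence is small (14 % of taxa differential)
while the *indirect* influence is large (96 % of taxa carry at least one
arm-unique delta-correlation with an immunity indicator — a rate dominated by
the unadjusted 120 × 69 test grid, which is exactly how the underlying
procedure behaves); and the SNV Venn recovers the planted 60 placebo-unique
vs 24 probiotic-unique changes after removing the 40 shared (time-related)
ones, reproducing the "more unique SNVs under placebo" ordering.

The same pipeline runs from the shell:

```sh
Rscript exec/deltaomics all --out demo --seed 11 --subjects 45
```

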