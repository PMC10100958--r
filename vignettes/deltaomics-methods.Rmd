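---
title: "Methods: paired two-arm multiomics analysis with planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired two-arm multiomics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deltaomics)
```

## The design and the inferential idea

A two-arm (placebo/probiotic), two-timepoint (baseline/endline) cohort
confounds two sources of change: time (diet drift, season, assay batch) and
treatment. Every analysis in this package therefore works on **per-subject
changes** and subtracts whatever the placebo arm reproduces:

* paired differential testing keeps a feature only if its change is *not*
  significant in the same direction in both arms;
* the delta-correlation ("indirect influence") screen removes
  feature–indicator correlations found with the same sign in both arms;
* the SNV attribution removes the intersection of the two arms' candidate
  SNV sets.

The three removals are the same logical operation — placebo subtraction — at
the level of abundances, associations and genetic variants respectively.

## Statistical kernels

**Shannon index** uses the natural logarithm over positive entries
(vegan's convention). **Bray–Curtis** is `Σ|xᵢ−yᵢ|/Σ(xᵢ+yᵢ)`; for the
metabolite layer, raw intensities are first converted to per-sample
proportions (logged when it happens) because BC on raw intensities is
scale-dependent.

**PERMANOVA** is implemented from distances only:
`SS_total = (1/N)Σ_{i<j} d²`, `SS_within = Σ_g (1/n_g)Σ_{i<j∈g} d²`,
`F = (SS_between/(a−1))/(SS_within/(N−a))`. The p-value is
`(1 + #{F_perm ≥ F_obs})/(1 + n_perm)` so that p ≥ 1/(n_perm+1); an
`exact = TRUE` mode enumerates all relabellings on small inputs and is
checked in the tests against an independent brute-force oracle and against
vegan's pseudo-F. A constant distance matrix raises an error ("zero
within-group variance") rather than returning an undefined F.

**Wilcoxon signed-rank** drops zero differences, uses an exact,
tie-aware null (dynamic programming over sign assignments, equivalent to
enumerating 2ⁿ patterns) for n ≤ 25 and a tie-corrected normal approximation
(no continuity correction) beyond. The two-sided p is
`P(|W−μ| ≥ |w_obs−μ|)`, which is exactly what brute-force enumeration
produces, ties included.

**Spearman** is the Pearson correlation of midranks; p from the
t-approximation `t = ρ√((n−2)/(1−ρ²))`, with an exact mode (full n!
enumeration, n ≤ 9) used by the oracle tests. Constant vectors are flagged
and the corresponding edges skipped.

The threshold in the indirect-influence screen is interpreted as a
**p-value cut-off** (p < 0.05), not a |ρ| cut-off: a correlation-magnitude
filter below 0.05 would retain only near-zero correlations, contradicting the
purpose of the analysis. The config key
`indirect$spearman_threshold_is_p_value` records this interpretation.

No multiple-testing correction is applied by default anywhere (raw p-values
are what the emulated analysis reports); a Benjamini–Hochberg switch exists
in both the differential and the indirect modules.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| VCF `min_quality` | 60 | QUAL, inclusive (vcftools' minQ is inclusive) |
| VCF `min_depth` | 100 | reads; FORMAT/DP preferred, INFO/DP fallback |
| SNV `prevalence` | 0.30 | fraction of the arm's paired subjects, inclusive |
| SNV `direction_scope` | either | gains and losses both count; `gained` mode available |
| QC `min_intensity` | 1000 | peak intensity |
| QC `min_prevalence` | 0.20 | per arm (a feature must pass in *each* group) |
| QC `max_rsd` | 0.20 | sd/mean of positive intensities, pooled samples |
| CLR pseudocount | 0.65 × sample min positive | multiplicative replacement |
| differential / indirect `alpha` | 0.05 | raw p threshold |
| `n_permutations` | 999 | PERMANOVA |

Multi-allelic VCF records are split and each ALT filtered independently
(conservative under the SNV-only rule); indels and multi-base alleles are
rejected. SNV identity includes both alleles, so the same position with a
different ALT is a different SNV. The prevalence denominator is the arm's
paired subjects — the only reading under which comparing the two arms'
candidate sets is coherent — with a pooled mode behind a flag.

### Filter-order bookkeeping

The metabolite QC report counts each removed feature exactly once, in the
fixed order intensity → prevalence → RSD: "intensity" removes features never
reaching the threshold in any sample, "prevalence" removes those failing the
per-group rule among the survivors, then the RSD cap applies. The order is a
reporting convention (the retained set is order-independent for these
particular rules' composition as implemented).

## The synthetic cohort: what it emulates, and what it does not

`cohort_config()` defaults state the emulated world: 45 subjects per arm
(90 subjects, 180 samples), four omics layers, 69 immunity indicators split
34 cytokine / 29 CBC / 6 lymphocyte.

* **Abundances** are log-normal per feature (sd 1.2 across features) with
  subject random effects (sd 0.8) and within-subject temporal noise
  (sd 0.3) — between-subject differences dominate temporal ones, the
  accepted picture for adult gut microbiomes; relative-abundance layers are
  closed to 1. Ten percent of entries are zeroed (detection dropouts),
  never on planted features.
* **Convergence** is centroid shrinkage: endline compositions of a group are
  moved a fraction κ toward the group's endline centroid (default
  κ_placebo = 0, κ_probiotic = 0.3). Shrinkage is affine on the simplex, so
  closure is preserved; expected within-group BC decreases strictly with κ.
* **Temporal drift** has two parts. A *diffuse* drift (per-feature
  N(0, 0.01) on the log scale) keeps the arms' shared time trend nonzero but
  an order of magnitude below within-subject noise; the *interpretable* time
  effect is carried by planted drift features at 1.5 × within-subject sd in
  both arms. The asymmetry with the planted treatment shifts (1.0 × sd,
  probiotic arm only) is deliberate: in the emulated study the time effect
  dwarfs the treatment effect (pseudo-F ≈ 14.6 vs ≈ 1.0 for bacterial
  composition), so a common drift *stronger* than the treatment shift is the
  faithful world. Setting the diffuse drift larger (an early draft used
  sd 0.05) confounds the convergence comparison, because the within-group
  dissimilarity test is hypersensitive (next section).
* **Planted delta-correlations** are drawn as exact bivariate-normal
  (feature-Δ, indicator-Δ) pairs *in composition space*: planted features get
  tight baselines around 2.5 % abundance and additive endline deltas, with
  the other features renormalised. This makes the planted Spearman equal the
  bivariate-normal value — `ρ_s = (6/π) asin(ρ/2)` — without attenuation by
  closure, which is why the plants live in the bacteria layer rather than
  going through the metabolite CLR chain. Arm-specific pairs are planted in
  the probiotic arm; shared pairs in both arms with the same sign.
* **SNVs**: a catalogue across `n_sgbs` SGB contigs; planted group-unique
  changes (count = rate × n_sgbs per arm; placebo default 3.0 vs probiotic
  1.2, preserving the "more unique SNVs under placebo" ordering) occur in
  ⌈prevalence × n⌉ hosts of one arm, shared changes in both arms, plus
  Poisson background changes per host that stay below the 30 % filter. One
  planted probiotic SNV is coupled to one immunity indicator
  (+1.5 sd for carriers) so the SNV–immunity association stage has a truth.
* The spec-style group rate has units "changes per SGB": planted group-level
  changes are cohort events (seen by a fixed host fraction), so a per-host
  reading applies only to the background rate.

What the generator does **not** emulate: phylogenetic structure,
compositional interactions between taxa, longitudinal autocorrelation beyond
two timepoints, batch effects, read-level noise. A green recovery test
therefore establishes that the pipeline recovers planted effects of the
stated geometry and size — not that it would behave identically on real
sequencing data.

## A known-red property: placebo convergence false positives

The convergence comparison follows the emulated analysis exactly: the
signed-rank pairs each subject-pair's baseline distance with the same pair's
endline distance. The C(45,2) = 990 pair deltas are not independent — two
pairs sharing a subject have correlation ≈ 1/3 (a parameter-free rank
argument for iid subject effects), inflating the test statistic's variance
roughly thirty-fold. Because rank tests are scale-invariant, *no* choice of
noise magnitudes fixes this: under any cohort with subject-level temporal
variation the placebo arm shows a "significant" dissimilarity change in
roughly half of replicates, with random sign (~25–50 % in each direction).
The alternative pairing unit (per-subject mean dissimilarity, n = 45) was
evaluated and is still miscalibrated (~27 %), because the cohort-level mean
dispersion change fluctuates at the same order as that test's detection
threshold. The acceptance property that the placebo false-positive rate stay
below 10 % is therefore unattainable in any realistic stated world and is
left red rather than weakened; the probiotic-arm detection property
(κ = 0.5 detected in ≥ 90 % of replicates) holds at 100 %. Practically: a
significant within-group-dissimilarity decrease in a single real cohort
should be read as descriptive, not confirmatory, unless the arms are
contrasted directly.

## Numerical and degenerate-input choices

* Inclusive thresholds throughout (QUAL ≥ 60, DP ≥ 100, prevalence ≥ 30 %,
  exactly 30 % passes).
* Permutation p-values include the observed statistic (+1/+1), so p = 0 is
  impossible; permutation draws take a mandatory seed.
* Tie handling: midranks everywhere; dense ranks in the species table
  (tied counts share a rank; ranks beyond the top-k render as NA).
* Zero differences in the signed-rank are dropped; an all-zero difference
  vector returns p = 1.
* Degenerate inputs error loudly: all-zero samples (Shannon, CLR,
  Bray–Curtis), groups with fewer than 2 members (PERMANOVA), fewer than
  6 paired subjects (differential testing, configurable), unmapped contigs
  or SGBs, samples missing from metadata (strict join — no silent cohort
  shrinkage).
* Percent changes are reported as the median of per-subject relative change
  (end−base)/base on raw values — a package convention, since the emulated
  analysis does not define its percentages; CLR values are used for
  metabolite testing, raw intensities for percent-change reporting.
* Classification of features significant in the placebo arm only defaults to
  `treatment_differential` (the placebo-subtraction rule read literally);
  `strict_probiotic_only = TRUE` restricts the differential call to
  probiotic-arm significance.
* Whether indicator deltas should be standardised before the
  immunity-change PERMANOVA is exposed as `diversity$standardize_deltas`
  (default off) rather than asserted.

## Build-or-buy

The statistical kernels (signed-rank, Spearman, PERMANOVA, Bray–Curtis,
CLR) are implemented in-package because they are the contribution under
test, and each is validated against an independent oracle (exhaustive
enumeration, closed forms, vegan, `stats::wilcox.test`/`cor.test`) in the
suite. VCF I/O uses a small internal reader for the minimal v4.2 subset the
pipeline consumes (presence/absence keys with QUAL/DP filtering and
multi-allelic splitting) rather than a full variant-annotation stack; the
round-trip contract `read(write(s)) == s` is property-tested. The rank-sum
test wraps `stats::wilcox.test`.

## Known limitations

* The indirect-influence count ratios are dominated by the unadjusted
  feature × indicator grid (≈ 1−(1−α)^{n_indicators} of features are
  implicated by chance); this mirrors the emulated procedure and is why the
  null-calibration test checks edge *fractions*, not feature counts.
* Exact Spearman enumeration is limited to n ≤ 9 and the exact signed-rank
  to n ≤ 25; beyond that the stated approximations apply.
* The SNV attribution treats a passing VCF record as presence (no genotype
  likelihoods), matching the upstream tooling it consumes.
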