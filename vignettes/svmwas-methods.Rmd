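---
title: "Methods: microbial structural-variant association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbial structural-variant association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(svmwas)
```

## The problem

Bacterial strains that look identical at the species-abundance level can
differ in which sub-genomic regions they carry. Two kinds of structural
variants (SVs) are visible in population-scale shotgun metagenomes once each
species' genome is split into 1-kbp bins and per-sample read depth is
tallied per bin: *deletion SVs* (dSVs), regions entirely absent from the
genomes carried by some subjects, and *variable SVs* (vSVs), regions whose
copy number varies continuously across subjects. Because such regions carry
genes (e.g. sialidases, glycosyl transferases) that can plausibly modulate
host immunity, their presence or dosage may associate with clinical outcomes
of immune checkpoint inhibitor (ICI) therapy — response (CR/PR vs SD/PD),
progression-free survival at 12 months (PFS12), immune-related adverse
events (irAEs) and overall survival (OS) — independently of species
abundance.

`svmwas` implements that analysis end to end: coverage-based SV genotyping,
SV dissimilarities and ordination, per-cohort regression association, and
random-effects meta-analysis with an explicit replication rule, plus a
synthetic multi-cohort generator that provides ground truth for every stage.

## Coverage normalization and species presence

Raw per-bin depth confounds sequencing effort, species abundance and copy
number. `normalize_coverage()` divides each (species, sample) row by its
median depth over non-zero bins, so 1 means "typical single-copy coverage
for this sample", and genotypes become invariant to rescaling any sample's
depths (a property the tests assert). A sample supports genotyping of a
species only when its median non-zero-bin depth is at least `depth_min`
(default 1 read/bin) **and** at least `breadth_min` (default 10%) of bins
are covered; otherwise every genotype for that species is missing rather
than a noisy guess. These two thresholds are our operational definition of
"sufficient coverage"; both are exposed as arguments.

## Calling and genotyping SVs

`detect_sv_regions()` works per species on the normalized matrix of present
samples, and only when the number of present samples reaches
`min_samp_cutoff(n)` — the smallest integer at least 10% of the cohort size
(so 17 for a 164-sample cohort and 34 for 338).

Per bin among present samples:

* a bin is **deletion-class** when the fraction of samples with ratio below
  `del_ratio` (default 0.25) lies inside `del_band` (default [0.25, 0.75]).
  The band keeps regions that are polymorphic: deleted in a substantial
  minority-to-majority of carriers. Bins deleted in more than 75% of
  samples are emitted as neither class — their genotype would be
  near-invariant and the "reference" state would itself be the rarity.
* a bin that is not deletion-class is **variable-class** when the
  cross-sample IQR of its ratio exceeds `var_thresh` (default 0.75). The
  IQR is robust to the heavy upper tail of copy-number ratios.

Adjacent same-class bins merge into segments; non-adjacent same-class
segments merge into one multi-segment region when their per-sample mean
signals correlate above `merge_r` (default 0.95), a greedy single-pass
stand-in for whatever clustering produced multi-segment regions in earlier
tools — we flag it as our construction rather than an assertion about any
particular implementation. A region satisfying both class rules is kept as
a dSV (deletion takes precedence; the bin-level else-if makes this
structural). Region ids are canonical strings
`species:start1-end1;start2-end2` in 0-based half-open kbp units and are the
key joining catalogs, profiles and results.

`genotype_sv()` calls a sample deleted (1) for a dSV when more than half the
region's bins fall below `del_ratio`, and gives a vSV genotype equal to the
mean normalized ratio over the region's bins. vSV genotypes stay on the
copy-ratio scale: downstream quartile coding is invariant to monotone
transforms, so standardization would change nothing and would cost
interpretability. `project_sv()` genotypes a *replication* cohort against
the unchanged discovery catalog — by construction identical to
`genotype_sv()`, which the tests assert as projection idempotence — so
discovery and replication effect sizes refer to the same regions.
`filter_sv_profile()` then drops SVs observed in fewer than 5% of all
samples; an SV at exactly 5% is retained.

## SV dissimilarity, ordination, variance partitioning

Sample-to-sample SV distance is the average of a binary Jaccard distance
over deletion indicators (1 − |A∩B|/|A∪B| of the two samples' deleted-SV
sets) and a scaled Canberra distance over vSV genotypes (the mean over
valid SVs of |x−y|/(x+y), excluding double zeros, matching the
community-ecology convention of `vegdist`; the raw-sum variant is available
behind `scaled = FALSE`). Missing genotypes are handled pairwise-complete:
each pair is compared over the SVs both samples carry. A pair sharing no
non-missing SV is undefined and flagged rather than silently imputed; in
the average, an entry undefined on one side falls back to the other.
Deletion indicators are oriented with 1 = deleted; orientation only
relabels the sets, and we document rather than agonize over it. Whether to
rescale the two matrices before averaging is genuinely open; we average
them as they are.

`sv_pcoa()` is classical metric scaling (double-centering of squared
distances, eigendecomposition, axes scaled by the square root of their
eigenvalues) via `stats::cmdscale`. Negative eigenvalues — expected, since
neither distance is Euclidean — are reported, excluded from variance
proportions, and not corrected.

`sv_permanova()` implements the permutational multivariate ANOVA directly:
sequential (order-of-entry) sums of squares from the Gower-centered matrix
via hat-matrix differences, pseudo-F per term, and
`P = (1 + #{permuted F ≥ observed F}) / (n_perm + 1)` under unrestricted
row permutation, deterministic given a seed. We implement the permutation
loop ourselves for three reasons: the permutation stream must be
reproducible from a single root seed; degenerate inputs with zero residual
sum of squares need an explicit F = ∞ convention so that permutation
counting stays exact (floating-point noise otherwise makes "≥" fail between
identical partitions); and small designs can be enumerated exhaustively
(`exact = TRUE`), which yields exact permutation P values — on a 6-sample
3/3 toy with zero within-group distance, exactly 2 of the 20 distinct
assignments reproduce the split, so P = 0.1. The sequential decomposition
is verified against `vegan::adonis2` in the tests. Sequential (Type-I)
sums of squares with raw-row permutation were chosen because that is the
convention of the `adonis` lineage this analysis style relies on; term
order is therefore part of the model specification.

`variance_partition()` enters named covariate *blocks* (e.g. the top five
abundance PCs from `abundance_pcs()`, then cohort, then age bin and gender)
as single multi-degree-of-freedom terms, so each block's R² is the
incremental variance it explains after the blocks before it. "Correcting
for microbial abundance" before axis-level group tests is implemented as
linear residualization of the PCo coordinates on the abundance PCs
(`residualize_axes()`), followed by one-way ANOVA (`axis_group_test()`);
the exact correction mechanism is not standardized anywhere, so we chose
the simplest transparent one and say so.

## Association models

All association models are per cohort, with age bin and gender as
covariates and listwise deletion of missing covariates or outcomes.

* **Species abundance** (`abundance_assoc()`): logistic
  `outcome ~ abundance + age_bin + gender`.
* **Species SV makeup** (`species_sv_makeup_assoc()`): the species'
  combined SV distance tested by PERMANOVA with
  `~ outcome + age_bin + gender`, skipped below 10 genotyped samples.
* **Single SVs, binary outcomes** (`sv_binary_assoc()`): logistic
  `outcome ~ SV + age_bin + gender`, requiring at least 10 usable subjects
  and at least 3 responders. dSVs enter as 0/1. vSVs are quartile-coded
  (codes 1–4 by the 25/50/75% type-7 quantiles, right-closed, so a value
  equal to a breakpoint falls in the lower bucket) and entered as a
  continuous 1–4 predictor, giving an interpretable OR per quartile step.
  Fewer than 4 distinct values make quartile coding meaningless and flag
  the feature instead.
* **Single SVs, OS** (`sv_survival_assoc()`): Cox
  `Surv(os_time, os_event) ~ SV + age_bin + gender`, requiring at least 20
  subjects and at least one event.
* **Descriptives**: Kaplan–Meier curves with a two-sided log-rank test
  (`km_logrank()`), and Spearman concordance of effect sizes over shared
  features between cancer types (`effect_concordance()`).

Age bins are ordinal categories entered as a single ordinal covariate; the
generator draws them directly as decade-style bins 1–4 because raw ages are
never used anywhere downstream. Complete separation and non-convergence
are *flagged and excluded from pooling* rather than Firth-corrected: no
correction is canonical here, and a flagged record preserves auditability
where a shrunken estimate would silently change the meta-analysis.

Benjamini–Hochberg FDR (`bh_fdr()`, `stats::p.adjust`) is applied within
(cohort, outcome, feature class) — dSVs, vSVs and abundance are corrected
independently, never pooled across classes (a construction test asserts
the per-class and pooled adjustments genuinely differ).

## Meta-analysis and the replication rule

`dl_pool()` is the DerSimonian–Laird moment estimator, written from its
closed form: fixed weights `w = 1/se²`, Cochran's
`Q = Σ w (β − β_FE)²`, `τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, random
weights `1/(se² + τ²)`, pooled SE `(Σw*)^(-1/2)`, heterogeneity P from
`χ²(k−1)`. A single cohort passes through unchanged with τ² undefined. The
tests pin the estimator to `metafor::rma(method = "DL")` and to a
closed-form hand case (betas 0 and 1 with SEs 0.1 give Q = 50, τ² = 0.49,
pooled 0.5 ± 0.5). DerSimonian–Laird was fixed as the estimator because it
is the conventional default of the random-effects tooling this analysis
style grew up with; REML or Paule–Mandel would change τ² slightly but is
out of scope.

A pooled association is a **replicated candidate** only when all three
hold: raw `P_meta ≤ 0.01` (not FDR-adjusted — the FDR rule below is the
single-cohort device); `P_heterogeneity > 0.05`; and per-cohort `P ≤ 0.2`
in at least two cohorts trending in the same direction, where direction is
the sign of beta and an exact zero counts as neither. Outcomes measured in
only one cohort use FDR-adjusted `P ≤ 0.1` instead
(`single_cohort_decision()`). All thresholds are applied with exactly the
stated inclusivity, and cohort order never changes any pooled field.

One consequence worth stating: the probability that a *null* pipeline run
yields zero replicated candidates decays with the number of SV–outcome
pairs tested, roughly `(1 − p)^m` with a per-test false-replication rate
`p ≈ 0.5–1%` under these thresholds. Zero-false-positive expectations are
therefore only meaningful for a stated family size; our null calibration
uses the matched null (the power-check design with its planted effect set
to zero, m = 2 tests per run).

## The synthetic generator

`simulate_cohorts()` emulates the statistical structure the pipeline
assumes: several cohorts with lognormal per-sample sequencing depth
(`depth_sd_log = 0.3`), per-sample species detection (`detect_prob = 0.9`;
undetected species have all-zero coverage and missing genotypes
downstream), planted dSVs (deleted in a configurable fraction of subjects;
their bins drop to zero expected depth) and planted vSVs (lognormal
per-subject copy ratio, spread `sd_log`), Poisson per-bin counts by default
with a negative-binomial option because real shotgun depth is
overdispersed (and `noise = "none"` for exact caller tests). Binary
outcomes come from logistic models on the *true* genotypes (deletions as
0/1; vSVs as centered within-cohort quartile codes) with age-bin, gender
and a random per-cohort intercept (`cohort_sd = 0.2`); OS is exponential
proportional hazards (baseline 1/365 events per day) with administrative
censoring at 730 days plus independent exponential dropout (rate 1/1500) —
the censoring structure is our choice, as none is canonical. Covariate
distributions default to uniform age bins and balanced gender,
configurable. One root seed drives everything; per-cohort streams are
derived deterministically, so identical config + seed is byte-identical.

What the generator does **not** emulate — and what green tests therefore do
not certify about real data: read-level artifacts (mappability, ambiguous
assignment between related species), compositionality and correlation
structure of abundances, GC/positional coverage waves, strain mixtures
within a sample, informative censoring, or correlated missingness between
clinical variables. It validates the machinery, not the biology.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to be
informative yet quick: type-I calibration uses 2,000 null tests per model
family (20 cohorts × 100 SVs at n = 100 for logistic and Cox; 2,000
999-permutation PERMANOVAs at n = 20); meta CI coverage uses k = 3 cohorts
of 300 over 200 replicates; effect recovery uses 3 cohorts of 600 over 50
replicate pipelines (planted log-OR 0.7, recovered within ±0.25); the
replication power and matched-null checks use 3 cohorts of 400 over 20
seeds. Distances are validated to 1e-12 against a brute-force double loop,
PCoA to 1e-8 against Euclidean reconstruction, and the DL estimator to
1e-9 against the closed form.

Numerical conventions: distance matrices are symmetrized by averaging with
their transpose before the diagonal is zeroed (guards against
last-bit asymmetry); PERMANOVA sums of squares within 1e-12 of zero
(relative to the total) are treated as exactly zero; 95% CIs use the
normal quantile 1.959963...; TSV output is tab-separated UTF-8 with `.`
decimal and `NA` for missing, fixed to avoid locale drift.

## Limitations

* Caller thresholds (`del_ratio`, the prevalence band, `var_thresh`,
  `merge_r`) are defensible defaults, not estimated quantities; all are
  arguments.
* The correlation-based multi-segment merge is order-dependent (greedy) and
  is not claimed to reproduce any specific historical clustering.
* Unrestricted permutation ignores cohort blocking; restricted schemes are
  out of scope.
* Lineage structure (SV population stratification within a species) is not
  adjusted for at the single-SV level.
* Flagging separation instead of penalizing discards information from
  extreme but real associations in small cohorts.
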