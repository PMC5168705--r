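---
title: "Methods: cfDNA methylation marker selection and ddMSP detection modelling"
author: "ddmspDetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA methylation marker selection and ddMSP detection modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmspDetect)
```

# The problem

Tumours shed DNA into plasma, and that circulating cell-free DNA (cfDNA)
carries the tumour's aberrant CpG methylation. A blood test for early breast
cancer can therefore be built from two kinds of signal: *how much* cfDNA a
plasma sample contains (cancer patients tend to run higher), and *which
fraction of it* is methylated at tumour-specific loci. This package
implements the complete analysis chain for such an assay:

1. **Marker discovery** from Infinium-style beta-value arrays of tumour and
   non-cancer samples (`computeGroupMeans()`, `selectCandidates()`);
2. **Absolute quantification** of droplet digital methylation-specific PCR
   (ddMSP) reactions: supervised amplitude thresholding, Poisson correction
   and copies/ml conversion (`optimizeAmplitudeThresholds()`,
   `poissonConcentration()`, `quantifyMarkers()`);
3. **Feature engineering** into the 15 per-sample model variables
   (`buildFeatureTable()`);
4. **Model selection**: a linear soft-margin SVM over every nonempty variable
   subset, scored by leave-one-out cross-validation, with an all-positive
   weight constraint (`exhaustiveSearch()`), plus the fixed published
   six-variable detection index (`fixedPublishedModel()`);
5. **Evaluation**: ROC/AUC, confusion metrics at a strict cutoff, stratified
   train/validation splitting, stage-trend and subtype tests
   (`evaluationReport()`, `jonckheereTerpstra()`, `subgroupReport()`);
6. A **synthetic cohort generator** (`simulateArrayData()`,
   `simulateRoster()`, `simulateDroplets()`) that reproduces the statistical
   structure this kind of study assumes, so every stage is testable without
   clinical samples.

# Marker selection from beta-value arrays

Candidate loci must be essentially unmethylated in non-cancer tissue and
blood (a cfDNA assay reads mostly leukocyte DNA), and methylated in tumours.
Four per-probe group means drive selection: `meanNC` over all non-cancer
samples, and `meanBC`, `meanLum`, `meanTN` over breast-cancer (BC), luminal
and triple-negative (TN) samples. Because the luminal and TN groups contain
very different proportions of cell-line and FFPE material, the BC-side means
are **balanced**: the unweighted average of the cell-line-stratum mean and
the FFPE-stratum mean (a pooled mean would be dominated by whichever
material is more numerous). On probes with `meanNC < 0.05`, four top-k
conditions select (a) 20 loci with the widest `meanBC - meanNC` gap, (b) 20
loci of lowest `meanNC` among probes with `meanBC > 0.6`, and (c)/(d) 50
luminal-dominant and 50 TN-dominant loci by the subtype-mean difference —
140 candidates when the conditions are disjoint. Ties break on the probe
identifier so selection is deterministic, and re-ordering the sample columns
cannot change the result.

Two points were genuinely open and are resolved as package defaults, each
behind a switch: `meanNC` is a plain (unbalanced) mean over all non-cancer
samples including blood — the assay requires markers silent in blood, and
balancing was only ever motivated by the luminal/TN material imbalance — and
`meanBC` is balanced like the subtype means for symmetry
(`computeGroupMeans(..., bcMean = "pooled")` gives the alternative).

# ddMSP quantification

A droplet is positive when its fluorescence amplitude falls in the half-open
interval `(lower, upper]`; the boundary rule is arbitrary but must be fixed,
and half-open keeps a droplet sitting exactly at the lower cutoff negative.
With `nPos` of `nTotal` droplets positive, Poisson partitioning gives the
mean copies per droplet `lambda = -log(1 - nPos/nTotal)`; copies in the
partitioned reaction are `lambda * nTotal`, and the volume chain (2 µl
template from a 20 µl elution of 0.9 ml plasma, 0.85 nl droplets — all
configurable in `defaultVolumes()`) converts to copies per ml plasma.
Saturated wells (every droplet positive) occur genuinely when
internal-control reactions are template-overloaded; the bare estimator
refuses them by default, while the cohort-level wrappers apply the
`(nPos - 0.5)/nTotal` continuity correction so processing does not abort.

## The amplitude-threshold search

Thresholds per marker are chosen *supervised*: candidate `(lower, upper]`
pairs are scored by the Mann–Whitney AUC of per-sample positive-droplet
fractions against the HV/BC labels (the positive fraction is a strictly
monotone transform of the concentration estimate, so this is exactly the
concentration AUC). Two numerical hazards shape the implementation:

* **Grid placement.** Candidates come from type-1 (inverse-ECDF) quantiles
  of the pooled amplitudes, which makes the search invariant under any
  strictly monotone rescaling of the fluorescence axis. But positive
  droplets may be anywhere from ~10% to ~0.01% of partitions depending on
  template load, so half of the 64 default probability points are spaced
  evenly and half are log-spaced in tail mass down to `1e-5` — otherwise no
  grid point falls between the clusters for low-load markers.
* **Selection noise.** Roughly 2000 correlated candidate pairs are compared
  on a small training set, so the raw argmax suffers a winner's curse: an
  interval slicing a random part of the positive cluster can beat the full
  cluster by luck, and the AUC is blind to intervals that add a
  near-constant negative-cluster count to every sample (a constant shift
  leaves ranks unchanged). The search therefore treats all pairs within
  three Hanley–McNeil standard errors of the maximum AUC as statistically
  indistinguishable, and among them maximises the penalised separation
  `delta - 0.15 * negMed`, where `delta` is the difference in class-median
  positive fractions and `negMed` the negative-class median fraction.
  Medians, not means: the biological concentration spread is heavy-tailed
  (lognormal with ~0.8 dex scatter), and a single outlier sample must not
  flip the separation criterion when the rank-based AUC is unaffected. The
  penalty strictly rejects intervals dipping into the negative cluster or
  rain (background without separation), while positive-cluster slivers lose
  because thinning the same droplets strictly shrinks `delta`. Residual
  exact ties resolve to the smallest `lower`, then the largest `upper`.

Per-marker positivity cutoffs on the copies/ml scale maximise the Youden
index over midpoints between consecutive sorted unique concentrations, with
the lowest optimal midpoint kept; a cutoff whose best J is zero is flagged
non-informative. All training-derived state (thresholds, cutoffs, epsilon,
volumes, the selected model) persists to a model-state JSON so an
independent validation cohort is processed with zero refitting.

# The 15 model variables

Per sample: the 12 methylation-marker log10 concentrations
(`log10(c + epsilon)`), their mean (`Mean12`), the log10 geometric mean of
the four internal-control concentrations (`IC` — arithmetic mean of the
log10 values, the assay's cfDNA concentration), and the count of
methylation-positive markers (`Npos`). Two conventions were open:

* **Epsilon.** Zero-positive wells need a finite log. The default is the
  copies/ml equivalent of half a copy per reaction under the configured
  volumes (≈ 5.56 copies/ml at defaults) — half of the assay's smallest
  countable signal, the digital analogue of a half-count pseudo-count.
* **Mean12 scale.** The mean of the 12 markers is taken on the log10 scale,
  consistent with every other model variable being a log10 quantity;
  `mean12Scale = "linear"` averages concentrations first.

# Detection model and exhaustive search

The detection index is a linear decision function; the published model is

```
0.62449·[RASGRF1] + 0.78110·[CPXM1] + 0.12115·[HOXA10] + 0.36760·[DACH1]
  + 0.65288·[Mean12] + 2.44704·[IC] − 6.98073
```

with samples called positive strictly above −0.07923. The kernel is linear
because the published model is a linear equation; features enter
unstandardised so fitted weights live on the printed scale, and the
soft-margin cost defaults to 1 (`fitLinearSVM(..., cost = )` to change; the
published regularisation setting is unreported, so printed coefficients
cannot be regenerated exactly and no attempt is made to).

Model selection enumerates all `2^V − 1` nonempty subsets of the searched
variables. Each subset is scored by the AUC of *pooled leave-one-out
decision values* — one model per held-out sample, all n out-of-fold scores
pooled into a single ROC — rather than averaged fold accuracies, because
AUC is the selection criterion throughout. The winner is the best-scoring
subset whose full-training-set refit has all weights strictly positive
(markers and cfDNA must point the same way for an interpretable index);
ties prefer fewer variables, then lexicographic mask order. If no subset
satisfies positivity the unconstrained best is returned with an explicit
flag. The full 15-variable search (32 767 subsets, each with n SVM refits)
is supported but is an hours-scale job at cohort size; the package's own
analyses search the published model's six variables.

# Evaluation

`rocAuc()` is the tie-corrected Mann–Whitney statistic; confusion metrics
use the same strict `>` positivity rule as classification. The
train/validation split is stratified by (class, stage) with
`round(n * fraction)` training draws per stratum — the published cohort
preset (133 HV / 145 BC with stages 4/47/31/22/9/32) splits into exactly
167 training and 111 validation samples. Subgroup reports bucket stages as
0–I, IIA, IIB–III and metastatic, computing per-bucket sensitivity and AUC
against the same split's HVs (the bucket-vs-HV comparison is assumed
split-internal). The stage trend uses a Jonckheere–Terpstra test, one-sided
in the direction "later stage → higher index" (the working hypothesis;
two-sided available), with tie-corrected variance, continuity-corrected
normal approximation, and exact permutation enumeration for n ≤ 12 (the
test suite verifies approximation–exact agreement within 0.02). Subtype
comparisons use `stats::kruskal.test()` and the age-bias check uses
Pearson's correlation via `stats::cor.test()` — standard tests are called,
not reimplemented; the JT test and the AUC are implemented in the package
because base R lacks the former and the latter must share exact tie
semantics with the threshold search.

# The synthetic cohort generator

The generator emulates the data-generating process the analysis assumes:

* **Arrays**: a low background (beta ≈ 0.02) with four planted probe
  classes engineered so each wins exactly one selection condition
  (strongly methylated everywhere in BC; moderately methylated with
  ultra-low non-cancer background; one subtype high / other background).
* **Cohort**: total cfDNA log10-normal per class — HV N(3.5, 0.25), BC
  N(4.1, 0.30) copies/ml, i.e. healthy medians around 3000
  genome-equivalents/ml with a several-fold elevation in cancer; ages
  uniform on 22–70 (HV) and 36–81 (BC); stage and subtype counts matching
  the published cohort exactly, DCIS pinned to stage 0.
* **Markers**: each marker's concentration is cfDNA × methylated fraction.
  The fraction is ~0.02 in background (HVs, and non-matching subtypes for
  the 4 luminal-dominant and 4 TN-dominant markers; luminal-HER2 counts as
  luminal) and rises with stage from 0.024 to 0.068 for active markers,
  with 0.8 dex lognormal per-sample scatter. Internal controls read cfDNA
  with 0.05 dex noise.
* **Droplets**: the positive count per well is Binomial(N, 1 − e^(−λ)) —
  the zero-truncation probability Poisson partitioning implies, and the
  quantity the package's Poisson correction inverts (drawing the count as
  Poisson(λN) instead would overshoot by λ/2 at internal-control loads and
  saturate near λ = 1). Amplitude clusters are Gaussian (negatives
  1000 ± 100, positives 8000 ± 300) with 0.1% of negative droplets re-drawn
  uniformly between the cluster means as "rain" — a handful per clean well,
  which is what makes the threshold search nontrivial without drowning
  few-copy signals.

These effect sizes were fixed by design targets, not fitted to data: the
internal controls are the strongest single features, single methylation
markers sit in the ~0.55–0.75 AUC band, and the combined six-variable model
separates classes with a training LOOCV AUC comfortably above 0.9 across
simulation replicates. That last target is deliberately placed slightly
above the corresponding published point estimate so the end-to-end property
holds robustly under simulation noise; consequently the generator's `IC`
and `Mean12` features run somewhat stronger than their published
counterparts while preserving the reported ordering (IC dominant, then
Mean12 and the positive-marker count, then single markers). What the
generator does **not** emulate: batch effects, probe cross-hybridisation,
bisulfite-conversion failure, well-to-well droplet-count variation,
multi-well merging, or any correlation between age and methylation — so
passing tests demonstrate the pipeline's statistical machinery, not
clinical performance.

# Problem sizes and runtime choices

The test suite runs every stage at sizes a laptop handles comfortably: the
planted-array checks use 1 500–20 000 probes; quantification-recovery uses
the full 278-sample cohort at 4 000 droplets/well; the end-to-end model
property runs 20 replicates of the published cohort composition at 2 000
droplets/well with the six-variable search; the exhaustive-search timing
check runs V = 10 at n = 60. The `table1_cohort` preset's default 12 000
droplets/well (a typical droplet-reader yield) generates ~53 million
droplets for the full cohort — fine for a single analysis run with a few
GB of memory, which is why the replicated tests trim the droplet count
(this changes Poisson counting noise only marginally, since counted copies
per reaction are droplet-count-independent).

# Known limitations

* The supervised threshold search assumes the training labels are reliable;
  it has no unsupervised cluster model to fall back on for label-free data.
* Weak markers (class fold-change below ~1.15) can defeat the penalised
  separation criterion's sliver protection at very small n; at the default
  cohort size the selection is stable.
* The published SVM's regularisation and scaling are unreported, so refit
  coefficients are not expected to reproduce the printed ones; the fixed
  model is provided verbatim for scoring instead.
* Exact JT enumeration is limited to n ≤ 14; larger samples use the normal
  approximation.

# A worked run

```{r, eval = FALSE}
cfg <- pipelineConfig(preset = "toy", seed = 1,
                      cohortConfig = list(nDroplets = 1500),
                      arrayConfig = list(nProbes = 2000))
res <- runPipeline(cfg)
bestModel(res$search)
res$evaluate$validation[c("auc", "sensitivity", "specificity")]
```
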