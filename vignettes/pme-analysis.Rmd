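---
title: "Proteomic characterization of the peritumor microenvironment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteomic characterization of the peritumor microenvironment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmesig)
```

## The problem

Hepatocellular carcinoma (HCC) grows in non-tumor liver tissue whose
molecular state — the *peritumor microenvironment* (PME) — conditions both
whether a tumor arises (occurrence) and how fast it progresses. `pmesig`
implements a complete label-free proteomic analysis of the PME: starting
from an iBAQ-like protein-intensity matrix over normal and peritumor liver
samples plus a clinical table, it derives

1. differentially expressed proteins (the altered PME proteome),
2. an occurrence signature (PME-O; proteins that discriminate peritumor
   from normal tissue by ROC) and a progression signature (PME-P; proteins
   whose abundance stratifies overall survival by log-rank),
3. per-patient risk indices (RI) aggregated over six functional categories
   (immunity, inflammation, angiogenesis, metabolism, proliferation and
   invasion, DNA damage and repair),
4. a three-marker logistic occurrence model and a three-marker Cox
   prognostic index (PI),
5. NMF consensus subtypes of the peritumor proteome with subtype–feature
   association tests.

All survival and classification statistics come from a self-contained
kernel (`roc_auc`, `km_estimate`, `logrank_test`, `cox_fit`,
`logistic_fit`, `fisher_exact`, `chi_square_test`, `correlation_test`)
written for this package and validated in the test suite against
independent references (`survival`, `pROC`, base `stats`).

## Preprocessing

`preprocess_abundance()` applies, in order: detection filtering (a protein
must be observed in at least 50% of all samples; a protein at exactly 50%
is kept), half-minimum imputation (each missing value becomes half the
protein's minimum observed intensity — the conventional stand-in for
values left-censored at the detection limit), quantile normalization
(every sample is mapped onto the across-sample mean of order statistics;
ties receive the mean of their target quantiles, so within-sample ranking
is preserved), and log2 transformation.

The order is a design choice the data force: imputation needs per-protein
minima on the raw linear scale, and quantile normalization assumes a
complete matrix. The detection fraction is computed over all samples
jointly, not per group. Applying the normalization twice changes nothing
(idempotence), which the tests verify to 1e-12.

## Differential analysis

`differential_test()` compares peritumor against normal per protein on the
log2 scale. The default is the equal-variance two-sample t test; an
empirical-Bayes moderated t (limma) is available via
`method = "moderated"`. The fold change is the linear-scale ratio of group
means, and a protein is called significant when the fold change exceeds
1.2 in either direction (> 1.2 or < 1/1.2) and p < 0.05. No multiple-testing
correction is applied by default — the rule is a screening filter, not an
inferential claim; Benjamini–Hochberg is available via `adjust = "BH"`.
Moderated and Student p-values coincide exactly only when per-protein
variances are equal; at realistic sample sizes the shrinkage keeps a
residual gap (a few percent at mid-range p), which the tests document.

## Signatures and risk indices

The occurrence arm ranks significant proteins by orientation-free AUC
(`max(AUC, 1 - AUC)`) for normal-vs-peritumor discrimination, keeps those
at or above 0.8, and caps the signature at 40 (ties broken by protein ID).
The progression arm median-splits the peritumor cohort on each protein's
abundance (values equal to the median go to the low stratum), tests the
strata by log-rank, keeps p ≤ 0.05, and caps at 52, ranked by p.

The per-patient risk index is a parameterized aggregation: protein *i*
contributes `w_i * s_ij` to patient *j*, where `w_i = 2 (AUC_i − 0.5)`
(occurrence) or `min(−log10 p_i, 4)` (progression), and `s_ij` is the
patient's abundance rescaled to [0, 10] across the peritumor cohort,
reversed for down-regulated proteins so every contribution is
risk-aligned. Category RIs sum the proteins of one functional category;
the total RI sums all categories; patients split into RI-high/RI-low at
the cohort median (values equal to the median go low, matching a strict
"greater than" rule). This formula is an explicit stand-in: the weights
and the rescale range are arguments of the design, not estimates, and no
numerical equivalence with any particular published RI scale is claimed.
A practical property worth knowing: chance log-rank hits that enter the
progression signature carry non-trivial weights, so the total RI is a
noisier readout of latent risk than the planted markers alone — the tests
therefore check aggregation on known markers and selection quality
separately.

## Prediction models

The occurrence model is a logistic regression (IRLS, deviance tolerance
1e-8) of tissue class on the log2 abundances of a three-marker panel; the
operating threshold maximizes Youden's J, with exact ties resolved toward
higher specificity. The prognostic index is defined as the Cox linear
predictor of a three-marker panel (Newton–Raphson on the Breslow partial
likelihood, gradient tolerance 1e-8, at most 100 iterations, step
halving); patients split at the median PI and are compared by
Kaplan–Meier curves and the log-rank test. Monotone likelihood and
separation are flagged on the fitted objects rather than silently
returned.

For the ROC of the PI the survival outcome must be dichotomized; the rule
used everywhere is: event = death before the cohort's median observed
follow-up, patients censored before that horizon are excluded, and the
exclusion count is reported on the model object and in the run log.

`cross_evaluate()` tests arm-specificity — each signature's proteins are
scored against *both* criteria and arm membership is cross-tabulated
against criterion attainment in two four-fold tables (chi-square and
Fisher exact; the chi-square is skipped on degenerate margins).
`validate_against_cohort()` applies a frozen model (no refit) to an
independent cohort.

## NMF consensus subtyping

The subtyping input is the significant differential proteome over
peritumor samples, shifted by its global minimum so NMF's non-negativity
holds. `nmf_factorize()` minimizes the Frobenius reconstruction error by
multiplicative updates (generalized Kullback–Leibler behind
`objective = "kl"`), stopping at a relative objective change below 1e-6 or
2000 iterations. W is initialized uniform(0, 1]-scaled from the run seed;
H is initialized as the row-scaled projection of the input onto W. The
projection makes every run exactly equivariant to sample permutation —
with a column-order-dependent random H the consensus matrix could not be
permutation-invariant, an invariant the package guarantees and tests.

`consensus_cluster()` repeats seeded restarts per candidate rank (2–6 by
default, 50 restarts), assigns each sample to its argmax basis component,
and accumulates co-assignment frequencies into a consensus matrix. Per
rank it reports the cophenetic correlation of the consensus
dissimilarity, the dispersion `mean((2C − 1)^2)`, and the area under the
consensus CDF with its increments across ranks. The chosen rank maximizes
the cophenetic coefficient (the CDF areas are emitted alongside so either
convention can be applied); final labels cut the average-linkage tree of
`1 − consensus`. A `weak_structure` flag is raised when even the best rank
shows unstable co-assignment — cophenetic below 0.95 or dispersion below
0.5; on structure-free input the cophenetic coefficient settles around
0.9 while planted block structure drives it to ~1.0, which is where those
cutoffs sit.

Subtype–feature tests use one-way ANOVA when a Brown–Forsythe check finds
homogeneous variances (p > 0.05) and Kruskal–Wallis otherwise; categorical
covariates use the Pearson chi-square. Subtypes with fewer than two
samples are excluded with a warning.

## The synthetic cohort generator

`generate_cohort()` produces the full data structure the analysis assumes,
with ground truth, so every stage is testable without access to any
patient-level dataset:

* **Abundances.** Per-protein log2 intensities are Gaussian with means ~
  N(20, 1.5²) and residual SDs from a scaled inverse-chi-square
  meta-distribution (d0 = 8, s0 = 0.45, floored at 0.25) — log-normal
  intensities spanning several orders of magnitude, as iBAQ data do.
* **Groups.** 34 normal and 61 peritumor samples by default. 8% of
  proteins (400 at the default 5000) are differential, shifted by a
  signed log2 fold change drawn from 1.5–2.5.
* **Markers.** Twelve occurrence markers are planted as strong, tight
  discriminators (fold change 3 up, residual SD 0.3, base abundance well
  above the detection limit); they reuse the panel symbols HSPA4L, VIL1,
  TYMP so the default model panels resolve. Six progression markers
  (CMPK2, TYMP, NADSYN1, …; TYMP deliberately shared between arms) are
  ordinary differential proteins that additionally drive survival.
* **Survival.** Exponential proportional hazards on the standardized
  progression-marker abundances, baseline log(2)/344 per day (median
  survival anchored at 344 days), |log-hazard| per SD drawn from 0.4–0.8
  by default, independent exponential censoring targeting 30%,
  administrative cutoff at 1609 days. Twelve simultaneous strong hazards
  would give the latent risk an SD of ~2.4 — a hazard spread beyond e^±5 —
  whose frailty attenuates every marginal association, so the default
  stays moderate.
* **Subtypes.** Three latent classes over peritumor samples; each class
  up-shifts its own disjoint block of 60 proteins by 1.2 log2 units.
* **Missingness.** Stochastic left-censoring: each cell goes missing with
  logistic probability (width 0.25 log2 units) around its sample's
  detection quantile at the target rate (10%); peritumor samples detect
  ~15% more of the borderline proteome (`detection_bias`), reproducing
  the deeper peritumor protein counts.
* **Clinical covariates.** AFP (log-normal, ng/mL), cirrhosis stage
  (ordinal 0–4), CYP2E1 activity (Gaussian, pmol/min/mg) are coupled to
  the standardized latent risk through a rank-preserving Gaussian copula
  (correlation 0.6 by default); tumor diameter and multiplicity are
  weakly coupled. The coupling strengths are free parameters of the
  generator, not estimates of any real joint distribution.

`null_cohort_config()` zeroes every planted effect — differentials,
markers, hazards, subtype blocks, detection bias, clinical coupling — and
is the basis of the calibration tests (null false-positive rate of the
differential screen; uniformity of null log-rank and subtype-feature
p-values).

What the generator does **not** emulate: peptide-level quantification,
batch or acquisition-order effects, correlated protein modules beyond the
planted blocks, non-proportional hazards, and informative censoring.
Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers the structure it assumes, not that real PME data meet
those assumptions.

## Numerical conventions

* ROC ties count 1/2 (Mann–Whitney midranks), so AUC is exactly the
  concordance probability; Youden ties resolve toward specificity.
* Fisher's exact test uses the minimum-likelihood two-sided convention
  (sum of hypergeometric probabilities ≤ the observed, with a 1 + 1e-7
  relative tolerance); degenerate margins give p = 1.
* The Pearson chi-square applies no continuity correction; a zero margin
  is an error.
* Cox ties use the Breslow approximation; Spearman's rho is Pearson on
  midranks with a t-approximation p.
* All stochastic steps (generator, NMF restarts, permutation nulls) are
  seeded; one pipeline seed fans out to stage seeds through the linear map
  `(seed * 48271 + offset) mod (2^31 − 1)`, so stages are independently
  reproducible and a repeated run is byte-identical.

## Problem sizes used in the checks

The test suite and the acceptance script exercise reduced but
structurally identical cohorts: 1200–2000 proteins (the planted fractions
scale with the proteome), the study's 34 + 61 samples, 20 Cox-recovery
replicates at n = 500, logistic recovery at n = 2000, ten prognostic
cohorts at n = 61, and consensus clustering with 15–25 restarts over
ranks 2–5. These sizes are the package's own choice of a thorough but
quick default; every operation accepts the full-size configuration
unchanged.

## Known limitations

* The RI formula is a documented stand-in (see above); its absolute scale
  is arbitrary.
* Rank selection by cophenetic maximum can prefer k = 2 on very weak
  structure; the CDF-area increments are reported so users can apply the
  alternative rule.
* The moderated t relies on limma's variance prior; with very few
  proteins the prior df estimate is noisy.
* `logrank_test` is the unweighted two-group test; no stratification or
  weighting, and the Cox fit offers Breslow ties only (adequate at the
  tie rates continuous abundances produce).
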