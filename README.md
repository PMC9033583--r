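# pmesig — proteomic signatures and subtyping of the peritumor microenvironment

`pmesig` is an R package for the proteomic characterization of the
**peritumor microenvironment (PME)** in hepatocellular carcinoma (HCC): the
non-tumor liver tissue surrounding a tumor, whose molecular state carries
information both about how the tumor arose (*occurrence*) and about how the
patient will fare (*progression*). It is aimed at computational biologists
analyzing label-free (iBAQ-like) proteomes of paired normal / peritumor
liver cohorts with clinical follow-up.

From a protein × sample intensity matrix and a clinical table the package
derives, end to end:

* **Altered PME proteome** — detection filtering (≥ 50% of samples),
  half-minimum imputation of detection-limit missingness, quantile
  normalization, log2 transform, then two-group differential screening with
  the rule *fold change > 1.2 (either direction) and p < 0.05* (Student's t
  by default, limma's moderated t optionally).
* **PME-O / PME-P signatures** — occurrence proteins ranked by
  orientation-free ROC AUC (`max(AUC, 1 − AUC) ≥ 0.8`, capped at 40);
  progression proteins by median-split log-rank on overall survival
  (`p ≤ 0.05`, capped at 52); overlap statistics between the arms.
* **Risk indices (RI)** — per-patient, per-functional-category aggregates
  (immunity, inflammation, angiogenesis, metabolism, proliferation and
  invasion, DNA damage and repair): each signature protein contributes
  `weight × abundance rescaled to [0,10]`, direction-aligned; patients
  split at the median total RI, and the split is tested against clinical
  covariates (AFP > 300 ng/mL, CYP2E1 > 1350 pmol/min/mg, …) by chi-square
  and Fisher exact tests.
* **Prediction models** — a three-marker logistic occurrence model
  (default panel HSPA4L + VIL1 + TYMP) with a Youden operating point, and a
  three-marker Cox **prognostic index** PI = Σ βᵢxᵢ (default panel
  CMPK2 + TYMP + NADSYN1) evaluated by median-PI Kaplan–Meier / log-rank
  and by ROC against early death; plus the occurrence↔progression
  cross-evaluation in four-fold tables.
* **PME subtypes** — NMF consensus clustering (multiplicative updates,
  Frobenius objective, seeded restarts) of the significant differential
  proteome over peritumor samples; rank chosen by cophenetic correlation
  with consensus-CDF areas reported; subtype–feature association tests.

The survival and classification statistics (ROC/AUC, Kaplan–Meier,
log-rank, Cox partial likelihood with Breslow ties, logistic IRLS, Fisher
exact by hypergeometric enumeration, Pearson chi-square, rank correlations)
are implemented in the package itself and cross-checked in the test suite
against `survival`, `pROC`, and base `stats`.

Because the underlying patient-level study data are not redistributable,
the package ships a **synthetic cohort generator** (`generate_cohort()`)
that emulates the study's structure — two-group log-normal abundances with
planted fold changes, planted occurrence/progression markers with
proportional-hazards effects, latent block subtypes, detection-limit
missingness, and copula-coupled clinical covariates — together with the
planted ground truth, so the whole pipeline is testable and every reported
number below is reproducible from a seed.

## Worked example

```r
library(pmesig)

co <- generate_cohort(cohort_config(n_proteins = 2000, seed = 1))
co
#> pme_cohort: 2000 proteins x 95 samples (34 normal / 61 peritumor)
#>   planted: 160 differential, 12 occurrence / 6 progression markers, 3 subtypes

m <- preprocess_abundance(co$abundance)   # filter, impute, quantile, log2
m
#> abundance_matrix: 1848 proteins x 95 samples [log2 scale], 0.0% missing

d <- differential_test(m, co$clinical)
sum(d$significant)
#> [1] 347

occ  <- select_occurrence_signature(d, m, co$clinical, co$category_map)
prog <- select_progression_signature(d, m, co$clinical, co$category_map)
signature_overlap(occ, prog)[c("n_shared", "union_size", "overlap_percent")]
#> $n_shared        [1] 2
#> $union_size      [1] 55
#> $overlap_percent [1] 3.64

compute_risk_profiles(occ, m, co$clinical)
#> Risk profiles (occurrence arm): 61 patients; total RI 160.66-228.38
#>   (IQR 184.05~197.41; mean 192.06)

fit_occurrence_model(m, co$clinical)
#> Occurrence model (logistic): HSPA4L + VIL1 + TYMP
#>   training AUC 1.000; sens 100.0% / spec 100.0% at Youden threshold

fit_prognostic_model(m, co$clinical)
#> Prognostic model (Cox PI): CMPK2 + TYMP + NADSYN1
#>   log-rank (median PI split): chi-square 15.514, p = 8.189e-05
#>   PI vs death before 264 d: AUC 0.759 (5 censored excluded)

V <- subtype_input_matrix(m, d, co$clinical)
consensus_cluster(V, k_range = 2:5, n_runs = 20, seed = 1)
#> NMF consensus clustering: k in {2,3,4,5}, 20 runs each
#>  k cophenetic dispersion cdf_area
#>  2     0.9933     0.7766   0.4579
#>  3     1.0000     1.0000   0.6776
#>  4     0.9998     0.9509   0.6912
#>  5     0.9981     0.8579   0.7233
#>   chosen k = 3 (max cophenetic); subtype sizes: 21/20/20
```

Reading the output: the preprocessed matrix keeps 1848 of 2000 proteins
(the rest fell below 50% detection); the differential screen flags 347
proteins (the 160 planted differentials, the planted subtype blocks, which
are real group differences, and the expected share of chance hits at raw
p < 0.05). The occurrence signature fills its cap of 40 with the planted
markers at its top; the two arms barely overlap. The three-marker
occurrence panel separates the groups perfectly at this planted effect
size, and the prognostic index splits survival at log-rank p ≈ 1e-4. The
consensus clustering recovers the three planted subtypes with a cophenetic
coefficient of 1.0 at k = 3.

`run_pipeline(run_config(...), "out/")` chains all stages, writes per-stage
TSV/JSON artifacts plus a run log and a `summary.json`, and is
byte-reproducible for a fixed seed. A thin command-line wrapper with the
same stages as subcommands (`simulate`, `preprocess`, `differential`,
`signatures`, `risk-index`, `occurrence-model`, `prognostic-model`,
`cross-eval`, `subtype`, `run-all`) is installed at
`system.file("cli/pme.R", package = "pmesig")`.

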