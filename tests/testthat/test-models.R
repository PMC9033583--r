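test_that("occurrence model separates groups on strongly planted markers", {
  fx <- fix_prep()
  om <- fit_occurrence_model(fx$m, fx$cohort$clinical)
  expect_gte(om$train_metrics$auc, 0.95)
  expect_true(all(om$fit$fitted > 0 & om$fit$fitted < 1))
  ## missing marker is named in the error
  expect_error(fit_occurrence_model(fx$m, fx$cohort$clinical,
                                    markers = c("HSPA4L", "NOPE")), "NOPE")
})

test_that("occurrence model AUC collapses to chance on shuffled labels", {
  fx <- fix_prep()
  aucs <- vapply(1:10, function(s) {
    cl <- fx$cohort$clinical
    cl$group <- withr::with_seed(700 + s, sample(cl$group))
    suppressWarnings(fit_occurrence_model(fx$m, cl)$train_metrics$auc)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("adding markers does not hurt training AUC on nested planted signal", {
  fx <- fix_prep()
  a1 <- fit_occurrence_model(fx$m, fx$cohort$clinical,
                             markers = "HSPA4L")$train_metrics$auc
  a3 <- fit_occurrence_model(fx$m, fx$cohort$clinical)$train_metrics$auc
  expect_gte(a3, a1 - 0.02)
})

test_that("prognostic model: PI is the Cox linear predictor and is scale-invariant", {
  fx <- fix_prep()
  pm <- fit_prognostic_model(fx$m, fx$cohort$clinical)
  expect_equal(unname(pm$pi),
               unname(drop(t(unclass(fx$m)[pm$markers, names(pm$pi)]) %*%
                             coef(pm$fit))), tolerance = 1e-10)
  ## doubling all covariates halves the betas and keeps the PI
  m2 <- abundance_matrix(unclass(fx$m) * 2, "log2")
  pm2 <- fit_prognostic_model(m2, fx$cohort$clinical)
  expect_equal(unname(coef(pm2$fit)), unname(coef(pm$fit)) / 2,
               tolerance = 1e-6)
  expect_equal(pm2$pi, pm$pi, tolerance = 1e-6)
  expect_identical(pm2$pi_group, pm$pi_group)
  ## groups come from the cohort median, independent of sample order
  expect_equal(sum(pm$pi_group == "high"),
               sum(pm$pi > median(pm$pi)))
})

test_that("prognostic model stratifies planted survival risk", {
  co <- generate_cohort(cohort_config(n_proteins = 800, seed = 12,
                                      n_progression_markers = 3,
                                      hazard_betas = c(0.8, 0.6, 0.5)))
  m <- preprocess_abundance(co$abundance)
  pm <- fit_prognostic_model(m, co$clinical,
                             markers = co$truth$progression_markers$protein_id)
  rho <- cor(pm$pi[names(co$truth$linear_predictor)],
             co$truth$linear_predictor, method = "spearman")
  expect_gte(rho, 0.7)
  expect_lt(pm$logrank$p_value, 0.05)
  expect_true(!is.null(pm$roc))
})

test_that("cross-evaluation detects arm-specific planted effects", {
  fx <- fix_prep()
  co <- fx$cohort
  occ <- select_occurrence_signature(fx$diff, fx$m, co$clinical, co$category_map)
  prog <- select_progression_signature(fx$diff, fx$m, co$clinical,
                                       co$category_map)
  ce <- cross_evaluate(occ, prog, fx$m, co$clinical)
  expect_equal(dim(ce$occurrence_table), c(2, 2))
  expect_equal(sum(ce$occurrence_table), nrow(occ) + nrow(prog))
  expect_lt(ce$occurrence_tests$fisher_p, 0.05)
  expect_lt(ce$progression_tests$fisher_p, 0.05)
  ## identical signatures: arm carries no information, association p = 1
  ce0 <- cross_evaluate(occ, occ, fx$m, co$clinical)
  expect_equal(ce0$occurrence_tests$fisher_p, 1)
  expect_equal(ce0$progression_tests$fisher_p, 1)
  ## degenerate margins keep the table well-formed and skip the chi-square
  expect_true(is.na(ce0$occurrence_tests$chisq_p) ||
                ce0$occurrence_tests$chisq_p == 1 ||
                !any(rowSums(ce0$occurrence_table) == 0))
})

test_that("frozen models evaluate unchanged on the training cohort and transfer to a replicate", {
  fx <- fix_prep()
  co <- fx$cohort
  om <- fit_occurrence_model(fx$m, co$clinical)
  self <- validate_against_cohort(om, fx$m, co$clinical)
  expect_equal(self$roc$auc, om$train_metrics$auc, tolerance = 1e-12)
  expect_equal(self$sensitivity, om$train_metrics$sensitivity)
  expect_equal(self$specificity, om$train_metrics$specificity)
  ## an independent cohort from the same generator family
  co2 <- generate_cohort(cohort_config(n_proteins = 1200, seed = 43))
  m2 <- preprocess_abundance(co2$abundance)
  val <- validate_against_cohort(om, m2, co2$clinical)
  expect_gte(val$roc$auc, 0.9)
  ## a cohort lacking one marker fails with its name
  m3 <- m2[setdiff(rownames(m2), "VIL1"), ]
  expect_error(validate_against_cohort(om, m3, co2$clinical), "VIL1")
})
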