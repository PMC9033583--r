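test_that("occurrence selection recovers planted markers and respects its contract", {
  fx <- fix_prep()
  co <- fx$cohort
  occ <- select_occurrence_signature(fx$diff, fx$m, co$clinical,
                                     co$category_map)
  expect_lte(nrow(occ), 40)
  expect_true(all(occ$auc >= 0.8))
  expect_true(all(occ$category %in% c("immunity", "inflammation",
                                      "angiogenesis", "metabolism",
                                      "proliferation_invasion",
                                      "dna_damage_repair")))
  ## planted strong discriminators rank inside the signature
  expect_gte(mean(co$truth$occurrence_markers$protein_id %in% occ$protein_id),
             0.9)
  ## impossible threshold yields an empty signature with a warning
  expect_warning(
    empty <- select_occurrence_signature(fx$diff, fx$m, co$clinical,
                                         co$category_map, auc_min = 1 + 1e-9),
    "empty occurrence signature")
  expect_equal(nrow(empty), 0)
})

test_that("progression selection recovers strongly planted hazard markers", {
  co <- generate_cohort(cohort_config(n_proteins = 1200, seed = 8,
                                      n_progression_markers = 3,
                                      hazard_betas = c(0.9, 0.8, 0.7)))
  m <- preprocess_abundance(co$abundance)
  d <- differential_test(m, co$clinical)
  prog <- select_progression_signature(d, m, co$clinical, co$category_map)
  expect_lte(nrow(prog), 52)
  expect_true(all(prog$logrank_p <= 0.05))
  expect_true(!is.unsorted(prog$logrank_p))
  expect_gte(mean(co$truth$progression_markers$protein_id %in%
                    prog$protein_id), 2 / 3)
  ## a constant protein is skipped (no valid split), not an error
  m2 <- m
  m2[1, ] <- 5
  d2 <- d; d2$significant[1] <- TRUE
  expect_false(rownames(m2)[1] %in%
                 select_progression_signature(d2, m2, co$clinical,
                                              co$category_map)$protein_id)
})

test_that("signature overlap arithmetic handles the edge cases", {
  expect_equal(signature_overlap(letters[1:5], letters[6:10])$overlap_percent, 0)
  expect_equal(signature_overlap(letters[1:5], letters[1:5])$overlap_percent, 100)
  ov <- signature_overlap(c("a", "b", "c"), c("c", "d"))
  expect_equal(ov$n_shared, 1)
  expect_equal(ov$union_size, 4)
  expect_equal(ov$overlap_percent, 25)
})

test_that("risk profiles aggregate weighted rescaled abundances per category", {
  fx <- fix_prep()
  co <- fx$cohort
  occ <- select_occurrence_signature(fx$diff, fx$m, co$clinical,
                                     co$category_map)
  risk <- compute_risk_profiles(occ, fx$m, co$clinical)
  prof <- risk$profiles
  cats <- setdiff(grep("^ri_", names(prof), value = TRUE), "ri_group")
  expect_equal(prof$total_ri, unname(rowSums(prof[cats])), tolerance = 1e-10)
  expect_true(all(prof$ri_group %in% c("high", "low")))
  ## strict median split: values equal to the median go low
  expect_equal(sum(prof$total_ri > median(prof$total_ri)),
               sum(prof$ri_group == "high"))
  ## planted high-risk patients (top tercile of the generating linear
  ## predictor) land in the RI-high group, on a strongly planted hazard
  ## cohort (betas 0.9 / 0.8 / 0.7)
  co2 <- generate_cohort(cohort_config(n_proteins = 1200, seed = 8,
                                       n_progression_markers = 3,
                                       hazard_betas = c(0.9, 0.8, 0.7)))
  m2 <- preprocess_abundance(co2$abundance)
  d2 <- differential_test(m2, co2$clinical)
  prog <- select_progression_signature(d2, m2, co2$clinical, co2$category_map)
  marker_sig <- prog[prog$protein_id %in%
                       co2$truth$progression_markers$protein_id, ]
  expect_gte(nrow(marker_sig), 2)
  risk_p <- compute_risk_profiles(marker_sig, m2, co2$clinical)
  lp <- co2$truth$linear_predictor[risk_p$profiles$sample_id]
  top <- lp >= quantile(lp, 2 / 3)
  tab <- table(factor(risk_p$profiles$ri_group, c("low", "high")),
               factor(top, c(FALSE, TRUE)))
  expect_lt(fisher_exact(unclass(tab))$p_value, 0.01)
})

test_that("degenerate and monotone risk-profile cases behave as documented", {
  ## identical abundances for every patient: flagged degenerate
  n <- 8
  m <- abundance_matrix(
    matrix(rep(c(4, 7), each = n), 2, n, byrow = TRUE,
           dimnames = list(c("a", "b"), paste0("s", 1:n))), "log2")
  cl <- data.frame(sample_id = colnames(m), group = "peritumor")
  sig <- data.frame(protein_id = c("a", "b"), arm = "occurrence",
                    category = c("immunity", "metabolism"),
                    auc = c(0.9, 0.85), logrank_p = NA, direction = "up")
  class(sig) <- c("pme_signature", class(sig))
  r <- compute_risk_profiles(sig, m, cl)
  expect_true(r$degenerate)
  expect_equal(length(unique(r$profiles$total_ri)), 1)
  ## a patient at the cohort maximum of every up marker attains the max RI
  withr::with_seed(60, {
    v <- matrix(rnorm(2 * n, 10), 2, n,
                dimnames = list(c("a", "b"), paste0("s", 1:n)))
    v[, 1] <- apply(v, 1, max) + 1
    m2 <- abundance_matrix(v, "log2")
    r2 <- compute_risk_profiles(sig, m2, cl)
    expect_equal(which.max(r2$profiles$total_ri), 1L)
    expect_equal(max(r2$profiles$total_ri),
                 sum(10 * 2 * (sig$auc - 0.5)), tolerance = 1e-10)
  })
  expect_error(compute_risk_profiles(sig[0, ], m, cl), "empty signature")
})

test_that("RI-clinical association crosses the median split against cutoffs", {
  fx <- fix_prep()
  co <- fx$cohort
  occ <- select_occurrence_signature(fx$diff, fx$m, co$clinical,
                                     co$category_map)
  risk <- compute_risk_profiles(occ, fx$m, co$clinical)
  ## covariate equal to the RI group itself: association is near-certain
  cl2 <- co$clinical
  cl2$self <- NA_real_
  idx <- match(risk$profiles$sample_id, cl2$sample_id)
  cl2$self[idx] <- ifelse(risk$profiles$ri_group == "high", 1, 0)
  res <- ri_clinical_association(risk, cl2, "self", 0.5)
  expect_lt(res$fisher_p, 1e-10)
  ## cutoff outside the data range: degenerate table, chi-square skipped
  res2 <- ri_clinical_association(risk, co$clinical, "afp_ng_ml", 1e9)
  expect_true(res2$degenerate)
  expect_true(is.na(res2$chisq_p))
  expect_equal(res2$fisher_p, 1)
  ## missing covariate values are excluded pairwise and counted
  cl3 <- co$clinical
  cl3$afp_ng_ml[idx[1:5]] <- NA
  res3 <- ri_clinical_association(risk, cl3, "afp_ng_ml", 300)
  expect_equal(res3$n_missing, 5)
  expect_equal(sum(res3$table), nrow(risk$profiles) - 5)
})

test_that("category comparison orders factors by mean RI and runs the omnibus test", {
  fx <- fix_prep()
  occ <- select_occurrence_signature(fx$diff, fx$m, fx$cohort$clinical,
                                     fx$cohort$category_map)
  risk <- compute_risk_profiles(occ, fx$m, fx$cohort$clinical)
  cmp <- compare_category_ri(risk)
  expect_false(is.unsorted(rev(cmp$summary$mean)))
  expect_true(is.numeric(cmp$kruskal_p) && cmp$kruskal_p >= 0 &&
                cmp$kruskal_p <= 1)
  expect_true(is.matrix(cmp$pairwise))
})
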