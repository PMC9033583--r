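test_that("NMF recovers an exact low-rank factorization and decreases monotonically", {
  withr::with_seed(70, {
    W0 <- matrix(runif(30 * 3), 30, 3)
    H0 <- matrix(runif(3 * 12), 3, 12)
    V <- W0 %*% H0
    errs <- vapply(1:10, function(s)
      nmf_factorize(V, 3, seed = s, max_iter = 5000, tol = 1e-12)$error, 0)
    expect_gte(sum(errs < 1e-6 * sum(V^2)), 8)
    f <- nmf_factorize(V, 3, seed = 1)
    expect_true(all(diff(f$error_trace) <= 1e-10))
    expect_true(all(f$W >= 0) && all(f$H >= 0))
  })
})

test_that("rank-1 NMF attains the SVD rank-1 error on a non-negative matrix", {
  withr::with_seed(71, {
    V <- matrix(rlnorm(20 * 8), 20, 8)
    f <- nmf_factorize(V, 1, seed = 2, max_iter = 5000, tol = 1e-12)
    sv <- svd(V)
    best <- sum((V - sv$d[1] * sv$u[, 1] %*% t(sv$v[, 1]))^2)
    expect_lte(f$error, best * 1.01)
  })
})

test_that("NMF input validation and determinism", {
  V <- matrix(1:12, 3, 4)
  expect_error(nmf_factorize(V - 7, 2), "negative")
  expect_error(nmf_factorize(V, 3), "k must satisfy")
  f1 <- nmf_factorize(V, 2, seed = 5)
  f2 <- nmf_factorize(V, 2, seed = 5)
  expect_identical(f1, f2)
})

test_that("consensus clustering is deterministic, permutation-equivariant, and single-run binary", {
  withr::with_seed(72, {
    ## two clean blocks over 16 samples
    V <- cbind(matrix(rlnorm(40 * 8, 3), 40, 8), matrix(rlnorm(40 * 8, 0), 40, 8))
    colnames(V) <- paste0("s", 1:16)
    c1 <- consensus_cluster(V, k_range = 2:3, n_runs = 8, seed = 11)
    c2 <- consensus_cluster(V, k_range = 2:3, n_runs = 8, seed = 11)
    expect_identical(c1$labels, c2$labels)
    expect_identical(c1$consensus, c2$consensus)
    ## consensus matrices are symmetric with unit diagonal, entries in [0,1]
    C <- c1$consensus[["2"]]
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), rep(1, 16))
    expect_true(all(C >= 0 & C <= 1))
    ## permuting samples permutes the consensus matrix the same way
    perm <- sample(16)
    c3 <- consensus_cluster(V[, perm], k_range = 2:2, n_runs = 8, seed = 11)
    ## same co-assignment structure: compare via the two clean blocks
    expect_equal(unname(c3$consensus[["2"]][colnames(V), colnames(V)]),
                 unname(consensus_cluster(V, k_range = 2:2, n_runs = 8,
                                          seed = 11)$consensus[["2"]]))
    ## single run gives a binary consensus
    c4 <- consensus_cluster(V, k_range = 2:2, n_runs = 1, seed = 3)
    expect_true(all(c4$consensus[["2"]] %in% c(0, 1)))
  })
})

test_that("best reconstruction error does not increase with rank", {
  withr::with_seed(73, {
    V <- matrix(rlnorm(30 * 14), 30, 14)
    colnames(V) <- paste0("s", 1:14)
    cons <- consensus_cluster(V, k_range = 2:5, n_runs = 5, seed = 2)
    expect_true(all(diff(cons$best_error) <= 1e-8))
  })
})

test_that("subtype feature tests find label-determined features and stay calibrated on noise", {
  withr::with_seed(74, {
    labels <- setNames(rep(1:3, each = 10), sprintf("P%03d", 1:30))
    cl <- data.frame(sample_id = names(labels), group = "peritumor",
                     survival_days = rexp(30, 0.01) + 1,
                     event = rbinom(30, 1, 0.7),
                     afp_ng_ml = rlnorm(30, 3, 1),
                     cirrhosis_stage = sample(0:4, 30, TRUE),
                     cyp2e1_activity = 100 * labels + rnorm(30, 1000, 1),
                     tumor_diameter_cm = rlnorm(30, 1.5, 0.4),
                     tumor_multiplicity = rbinom(30, 1, 0.3))
    res <- subtype_feature_tests(labels, cl)
    expect_true(all(c("feature", "test", "statistic", "p_value") %in% names(res)))
    ## cyp2e1 is a deterministic function of the label
    expect_lt(res$p_value[res$feature == "cyp2e1_activity"], 1e-6)
    ## survival is independent of the label
    expect_gt(res$p_value[res$feature == "survival_days"], 0.01)
    ## a subtype with < 2 samples is excluded with a warning
    labels2 <- labels; labels2[1:9] <- 2
    expect_warning(subtype_feature_tests(labels2, cl), "excluded")
  })
})

test_that("subtype input matrix is the shifted significant differential block", {
  fx <- fix_prep()
  V <- subtype_input_matrix(fx$m, fx$diff, fx$cohort$clinical)
  expect_true(all(V >= 0))
  expect_equal(nrow(V), sum(fx$diff$significant &
                              fx$diff$protein_id %in% rownames(fx$m)))
  expect_equal(ncol(V), sum(fx$cohort$clinical$group == "peritumor"))
})
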