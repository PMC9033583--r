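mk_abn <- function(v, nr, nc) {
  abundance_matrix(matrix(v, nr, nc,
                          dimnames = list(paste0("p", seq_len(nr)),
                                          paste0("s", seq_len(nc)))),
                   "linear")
}

test_that("detection filter keeps proteins at exactly the threshold", {
  m <- abundance_matrix(matrix(c(1, NA, NA,
                                 2, 5, NA,
                                 3, NA, NA,
                                 4, 6, 7), 3, 4,
                               dimnames = list(paste0("p", 1:3),
                                               paste0("s", 1:4))), "linear")
  ## p1 detected 4/4, p2 detected 2/4 (kept at 0.5), p3 detected 1/4 (dropped)
  kept <- filter_by_detection(m, 0.5)
  expect_identical(rownames(kept), c("p1", "p2"))
  ## min_frac 1 keeps only complete rows
  expect_identical(rownames(filter_by_detection(m, 1)), "p1")
  expect_warning(filter_by_detection(m[3, , drop = FALSE], 1), "no proteins")
  expect_error(filter_by_detection(m, 0), "min_frac")
})

test_that("half-minimum imputation applies the stated rule and only to missing cells", {
  m <- abundance_matrix(matrix(c(2, NA, 8, 4, 6, 1), 2, 3, byrow = TRUE,
                               dimnames = list(c("a", "b"),
                                               c("s1", "s2", "s3"))), "linear")
  out <- impute_half_min(m)
  expect_equal(unclass(out)["a", ], c(s1 = 2, s2 = 1, s3 = 8))
  expect_equal(unclass(out)["b", ], c(s1 = 4, s2 = 6, s3 = 1))
  ## the imputed value is the row minimum after imputation
  expect_equal(min(unclass(out)["a", ]), 1)
  ## all-missing row errors
  m2 <- abundance_matrix(matrix(c(NA_real_, NA_real_), 1, 2,
                                dimnames = list("x", c("s1", "s2"))), "linear")
  expect_error(impute_half_min(m2), "all-missing")
})

test_that("quantile normalization equalizes column distributions", {
  m <- mk_abn(c(1, 2, 3, 4, 5, 6), 3, 2)
  out <- quantile_normalize(m)
  expect_equal(unname(unclass(out)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(out)[, 2]), c(2.5, 3.5, 4.5))
  ## random complete matrix: sorted columns identical to 1e-12, rank order kept
  withr::with_seed(40, {
    m2 <- mk_abn(rlnorm(200, 10, 1), 40, 5)
    q <- unclass(quantile_normalize(m2))
    s <- apply(q, 2, sort)
    expect_lt(max(abs(s - s[, 1])), 1e-12)
    for (j in 1:5)
      expect_identical(order(q[, j]), order(unclass(m2)[, j]))
    ## idempotent from the second application onward
    q2 <- unclass(quantile_normalize(as_abn_linear(q)))
    expect_equal(q2, q, tolerance = 1e-12)
  })
  ## identical-distribution columns are unchanged up to reordering
  m3 <- mk_abn(c(1, 2, 3, 3, 1, 2), 3, 2)
  out3 <- unclass(quantile_normalize(m3))
  expect_equal(sort(out3[, 1]), sort(unclass(m3)[, 1]))
  ## single-sample matrix is the identity
  m4 <- mk_abn(c(5, 1, 9), 3, 1)
  expect_equal(unclass(quantile_normalize(m4)), unclass(m4))
})

test_that("quantile normalization matches limma's midrank-tie dialect", {
  skip_if_not_installed("limma")
  withr::with_seed(41, {
    v <- matrix(sample(1:30, 60, replace = TRUE), 12, 5,
                dimnames = list(paste0("p", 1:12), paste0("s", 1:5)))
    mine <- unclass(quantile_normalize(abundance_matrix(v * 1.0, "linear")))
    ref <- limma::normalizeQuantiles(v, ties = TRUE)
    expect_equal(mine, ref, tolerance = 1e-12, ignore_attr = TRUE)
  })
})

test_that("log2 transform and the full pipeline keep identities and ordering", {
  m <- mk_abn(c(1, 8, 2, 4), 2, 2)
  lt <- log2_transform(m)
  expect_equal(unname(unclass(lt)[, 1]), c(0, 3))
  expect_equal(2^unclass(lt), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(log2_transform(mk_abn(c(0, 1, 2, 3), 2, 2)), "strictly positive")
  expect_error(log2_transform(lt), "linear")
  co <- fix_cohort()
  p <- preprocess_abundance(co$abundance)
  expect_identical(attr(p, "scale"), "log2")
  expect_false(anyNA(p))
  ## ordering preserved: retained proteins appear in original order
  expect_identical(rownames(p),
                   rownames(co$abundance)[rownames(co$abundance) %in% rownames(p)])
  expect_identical(colnames(p), colnames(co$abundance))
})
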