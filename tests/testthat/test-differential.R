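## tiny two-group matrix builder on the log2 scale
mk_log2 <- function(values, groups) {
  nr <- nrow(values)
  m <- abundance_matrix(
    matrix(values, nr, ncol(values),
           dimnames = list(paste0("p", seq_len(nr)),
                           paste0("s", seq_len(ncol(values))))), "log2")
  list(m = m,
       clinical = data.frame(sample_id = colnames(m), group = groups))
}

test_that("student p equals the textbook pooled-variance t on a 3+3 fixture", {
  vals <- rbind(c(5.1, 5.9, 5.4, 7.2, 7.9, 7.1),
                c(6.0, 6.1, 5.9, 6.0, 6.2, 6.1))
  fx <- mk_log2(vals, rep(c("normal", "peritumor"), each = 3))
  d <- differential_test(fx$m, fx$clinical)
  for (i in 1:2) {
    tt <- t.test(vals[i, 4:6], vals[i, 1:3], var.equal = TRUE)
    expect_equal(d$p_value[i], tt$p.value, tolerance = 1e-12)
  }
  ## fold change is the linear-scale ratio of group means
  expect_equal(d$fold_change[1],
               mean(2^vals[1, 4:6]) / mean(2^vals[1, 1:3]), tolerance = 1e-12)
  expect_equal(d$log2fc, log2(d$fold_change))
})

test_that("identical groups give p = 1 with a zero-variance flag and no calls", {
  vals <- rbind(rep(3, 6), rep(7, 6))
  fx <- mk_log2(vals, rep(c("normal", "peritumor"), each = 3))
  d <- differential_test(fx$m, fx$clinical)
  expect_equal(d$p_value, c(1, 1))
  expect_true(all(d$zero_variance))
  expect_false(any(d$significant))
})

test_that("swapping group labels negates log2fc and preserves p", {
  withr::with_seed(50, {
    vals <- matrix(rnorm(80, 10), 8, 10)
    g1 <- rep(c("normal", "peritumor"), each = 5)
    g2 <- rep(c("peritumor", "normal"), each = 5)
    fx1 <- mk_log2(vals, g1); fx2 <- mk_log2(vals, g2)
    d1 <- differential_test(fx1$m, fx1$clinical)
    d2 <- differential_test(fx2$m, fx2$clinical)
    expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
    expect_equal(d1$p_value, d2$p_value, tolerance = 1e-12)
  })
})

test_that("significance obeys the two-sided fold-change + p rule", {
  co <- fix_prep()
  d <- co$diff
  expect_equal(d$significant,
               (d$fold_change > 1.2 | d$fold_change < 1 / 1.2) &
                 d$p_value < 0.05 & !d$zero_variance)
  expect_equal(d$direction, ifelse(d$log2fc >= 0, "up", "down"))
  ## planted differentials with |fc| >= 2 are recovered with high sensitivity
  tr <- co$cohort$truth$de
  strong <- tr$protein_id[abs(tr$log2fc) >= 1 & tr$protein_id %in% d$protein_id]
  expect_gte(mean(strong %in% d$protein_id[d$significant]), 0.9)
})

test_that("moderated and student t agree in the large-replicate limit", {
  ## in the limit the per-protein variances coincide and shrinkage is a
  ## no-op; construct that limit exactly by scaling every row to unit pooled
  ## variance, leaving only the (vanishing) prior-df difference
  withr::with_seed(51, {
    n <- 100
    g <- rep(c("normal", "peritumor"), each = n)
    vals <- matrix(rnorm(200 * 2 * n, 0, 0.5), 200, 2 * n)
    vals <- t(apply(vals, 1, function(v) {
      ctr <- ave(v, g)
      sp <- sqrt(sum((v - ctr)^2) / (2 * n - 2))
      ctr + (v - ctr) / sp
    })) + 10
    fx <- mk_log2(vals, g)
    ds <- differential_test(fx$m, fx$clinical, method = "student")
    dm <- differential_test(fx$m, fx$clinical, method = "moderated")
    expect_lt(max(abs(ds$p_value - dm$p_value)), 0.01)
    ## and the raw-noise agreement improves with replicates
    gap <- function(n) {
      v <- matrix(rnorm(200 * 2 * n, 10, 0.5), 200, 2 * n)
      fx <- mk_log2(v, rep(c("normal", "peritumor"), each = n))
      ds <- differential_test(fx$m, fx$clinical, method = "student")
      dm <- differential_test(fx$m, fx$clinical, method = "moderated")
      max(abs(ds$p_value - dm$p_value))
    }
    expect_lt(gap(150), gap(8))
  })
})

test_that("volcano table mirrors the records one-to-one", {
  d <- fix_prep()$diff
  v <- volcano_table(d)
  expect_equal(nrow(v), nrow(d))
  expect_equal(v$significant, d$significant)
  expect_equal(v$neg_log10_p, -log10(pmax(d$p_value, 1e-300)))
})

test_that("identified-protein counts separate groups with planted detection bias", {
  co <- fix_cohort()
  ci <- count_identified(co$abundance, co$clinical)
  expect_equal(nrow(ci$counts), ncol(co$abundance))
  ## complete sample counts all proteins
  m0 <- generate_cohort(cohort_config(n_proteins = 100, missing_rate = 0,
                                      seed = 4))
  ci0 <- count_identified(m0$abundance, m0$clinical)
  expect_true(all(ci0$counts$n_identified == 100))
  ## peritumor carries more planted up-shifts, hence more detections
  expect_gt(ci$group_means[["peritumor"]], ci$group_means[["normal"]])
  expect_lt(ci$p_value, 0.05)
  ## empty group errors
  cl_bad <- co$clinical; cl_bad$group <- "peritumor"
  expect_error(count_identified(co$abundance, cl_bad), "both groups")
})
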