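## shared fixtures, built once per test run and memoized

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

## standard planted cohort at reduced proteome size (structure as defaults)
fix_cohort <- function() memo("cohort", function()
  generate_cohort(cohort_config(n_proteins = 1200, seed = 42)))

## preprocessed matrix + differential table for the standard cohort
fix_prep <- function() memo("prep", function() {
  co <- fix_cohort()
  m <- preprocess_abundance(co$abundance)
  list(cohort = co, m = m,
       diff = differential_test(m, co$clinical))
})

## fully null cohort (no planted structure anywhere)
fix_null <- function() memo("null", function()
  generate_cohort(null_cohort_config(n_proteins = 800, seed = 7)))

## small survival fixture with ties and censoring
fix_surv <- function() list(
  time = c(2, 3, 3, 5, 7, 8, 8, 11, 12, 14, 15, 15, 17, 20, 21, 24),
  event = c(1, 1, 0, 1, 1, 1, 0, 1, 0, 1, 1, 1, 0, 1, 0, 1),
  group = rep(c("a", "b"), 8))

as_abn_linear <- function(v) abundance_matrix(v, "linear")

## brute-force AUC by explicit pair enumeration (ties count 1/2)
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
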