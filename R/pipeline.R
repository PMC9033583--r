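#' Pipeline run configuration
#'
#' Bundles every stage parameter of the end-to-end PME analysis with
#' defaults matching the screening rules the pipeline implements: detection
#' >= 0.5, fold change 1.2, p 0.05, occurrence AUC >= 0.8 capped at 40,
#' progression log-rank p <= 0.05 capped at 52, AFP cutoff 300 ng/mL,
#' CYP2E1 cutoff 1350 pmol/min/mg, survival cutoff 344 days, NMF ranks 2-6
#' with 50 restarts. Input is either a synthetic [cohort_config()] or a
#' directory holding `abundance.tsv`, `clinical.csv` and (optionally)
#' `category_map.tsv`.
#'
#' @param cohort a [cohort_config()] (used when `input_dir` is NULL).
#' @param input_dir directory with on-disk input files, or NULL.
#' @param min_detect,quantile preprocessing parameters.
#' @param method,fc_threshold,p_threshold differential parameters.
#' @param auc_min,occ_max,prog_p_max,prog_max signature parameters.
#' @param afp_cutoff,cyp2e1_cutoff,survival_cutoff RI-association cutoffs.
#' @param n_markers panel size for both prediction models (top-ranked
#'   signature proteins).
#' @param k_range,n_runs consensus-NMF parameters.
#' @param seed master seed; stage seeds are derived as
#'   `(seed * 48271 + offset) mod (2^31 - 1)` with offset 1 for the
#'   generator and 2 for consensus clustering.
#' @return list of class `pme_run_config`.
#' @export
run_config <- function(cohort = cohort_config(), input_dir = NULL,
                       min_detect = 0.5, quantile = TRUE,
                       method = "student", fc_threshold = 1.2,
                       p_threshold = 0.05, auc_min = 0.8, occ_max = 40,
                       prog_p_max = 0.05, prog_max = 52, afp_cutoff = 300,
                       cyp2e1_cutoff = 1350, survival_cutoff = 344,
                       n_markers = 3, k_range = 2:6, n_runs = 50, seed = 1) {
  cfg <- as.list(environment())
  if (is.null(input_dir) && !inherits(cohort, "cohort_config"))
    stop("either a cohort_config or an input_dir is required")
  structure(cfg, class = "pme_run_config")
}

#' Run the full PME analysis pipeline
#'
#' simulate-or-load -> preprocess -> differential -> signatures and risk
#' indices -> occurrence/prognostic models -> cross-evaluation -> NMF
#' consensus subtypes -> report. Every stage writes its artifact under
#' `output_dir` (write-once), a run log records every parameter and
#' decision, and `summary.json` collects the headline quantities. Identical
#' config + seed gives a byte-identical summary.
#'
#' @param config a [run_config()].
#' @param output_dir output directory (created; existing files overwritten).
#' @return invisible list with the in-memory stage results plus `summary`.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pme_run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(output_dir, "run_log.txt")
  cat("", file = log_path)
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  logf("pme pipeline run; master seed %d", config$seed)

  ## stage 1: cohort
  if (is.null(config$input_dir)) {
    gseed <- derive_seed(config$seed, 1L)
    cc <- config$cohort; cc$seed <- gseed
    cohort <- generate_cohort(cc)
    write_cohort(cohort, file.path(output_dir, "cohort"))
    m_raw <- cohort$abundance; clinical <- cohort$clinical
    category_map <- cohort$category_map
    logf("stage cohort: synthetic, %d proteins x %d samples, generator seed %d",
         nrow(m_raw), ncol(m_raw), gseed)
  } else {
    m_raw <- read_abundance(file.path(config$input_dir, "abundance.tsv"))
    clinical <- read_clinical(file.path(config$input_dir, "clinical.csv"))
    cm_path <- file.path(config$input_dir, "category_map.tsv")
    category_map <- if (file.exists(cm_path)) read_category_map(cm_path) else NULL
    cohort <- NULL
    logf("stage cohort: loaded from %s", config$input_dir)
  }

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## stage 2: preprocess
  m <- run_stage("preprocess", preprocess_abundance(
    m_raw, min_detect = config$min_detect, quantile = config$quantile))
  logf("stage preprocess: detection >= %.2f, quantile = %s; %d proteins retained",
       config$min_detect, config$quantile, nrow(m))

  ## stage 3: differential
  counts <- run_stage("differential", count_identified(m_raw, clinical))
  diff <- run_stage("differential", differential_test(
    m, clinical, method = config$method, fc_threshold = config$fc_threshold,
    p_threshold = config$p_threshold))
  write_tsv(as.data.frame(diff), file.path(output_dir, "differential.tsv"))
  write_tsv(volcano_table(diff), file.path(output_dir, "volcano.tsv"))
  logf("stage differential: method %s, fc > %.2f, p < %.2f; %d significant",
       config$method, config$fc_threshold, config$p_threshold,
       sum(diff$significant))

  ## stage 4: signatures + risk indices
  occ_sig <- run_stage("signatures", suppressWarnings(
    select_occurrence_signature(diff, m, clinical, category_map,
                                auc_min = config$auc_min,
                                max_n = config$occ_max)))
  prog_sig <- run_stage("signatures", suppressWarnings(
    select_progression_signature(diff, m, clinical, category_map,
                                 p_max = config$prog_p_max,
                                 max_n = config$prog_max)))
  write_tsv(as.data.frame(occ_sig), file.path(output_dir, "signature_occurrence.tsv"))
  write_tsv(as.data.frame(prog_sig), file.path(output_dir, "signature_progression.tsv"))
  overlap <- signature_overlap(occ_sig, prog_sig)
  logf("stage signatures: occurrence %d (AUC >= %.2f), progression %d (p <= %.2f); overlap %.2f%%",
       nrow(occ_sig), config$auc_min, nrow(prog_sig), config$prog_p_max,
       overlap$overlap_percent)

  risk <- list(occurrence = NULL, progression = NULL)
  assoc <- NULL
  for (arm in c("occurrence", "progression")) {
    sig <- if (arm == "occurrence") occ_sig else prog_sig
    if (nrow(sig)) {
      risk[[arm]] <- run_stage("risk-index",
                               compute_risk_profiles(sig, m, clinical))
      write_tsv(risk[[arm]]$profiles,
                file.path(output_dir, paste0("risk_", arm, ".tsv")))
    } else logf("stage risk-index: %s signature empty, skipped", arm)
  }
  if (!is.null(risk$occurrence)) {
    assoc <- list(
      afp = ri_clinical_association(risk$occurrence, clinical, "afp_ng_ml",
                                    config$afp_cutoff),
      cyp2e1 = ri_clinical_association(risk$occurrence, clinical,
                                       "cyp2e1_activity", config$cyp2e1_cutoff))
    logf("stage risk-index: occurrence RI vs AFP>%g fisher p = %.4g; vs CYP2E1>%g fisher p = %.4g",
         config$afp_cutoff, assoc$afp$fisher_p, config$cyp2e1_cutoff,
         assoc$cyp2e1$fisher_p)
  }

  ## stage 5: prediction models (panels = top-ranked signature proteins)
  occ_model <- prog_model <- cross <- NULL
  if (nrow(occ_sig) >= 1) {
    panel <- utils::head(occ_sig$protein_id, config$n_markers)
    occ_model <- run_stage("occurrence-model",
                           fit_occurrence_model(m, clinical, markers = panel))
    write_model_json(occ_model, file.path(output_dir, "occurrence_model.json"))
    logf("stage occurrence-model: panel %s; AUC %.4f",
         paste(panel, collapse = "+"), occ_model$train_metrics$auc)
  } else logf("stage occurrence-model: skipped (empty signature)")
  if (nrow(prog_sig) >= 1 && !is.null(risk$progression)) {
    panel <- utils::head(prog_sig$protein_id, config$n_markers)
    prog_model <- run_stage("prognostic-model",
                            fit_prognostic_model(m, clinical, markers = panel))
    write_model_json(prog_model, file.path(output_dir, "prognostic_model.json"))
    logf("stage prognostic-model: panel %s; log-rank p %.4g (PI median split); progression ROC outcome: death before median follow-up %.0f d, %d censored excluded",
         paste(panel, collapse = "+"), prog_model$logrank$p_value,
         prog_model$horizon, prog_model$n_excluded)
  } else logf("stage prognostic-model: skipped")
  if (nrow(occ_sig) && nrow(prog_sig)) {
    cross <- run_stage("cross-eval",
                       cross_evaluate(occ_sig, prog_sig, m, clinical,
                                      auc_min = config$auc_min,
                                      p_max = config$prog_p_max))
    jsonlite::write_json(
      list(occurrence = list(table = unclass(cross$occurrence_table),
                             tests = cross$occurrence_tests),
           progression = list(table = unclass(cross$progression_table),
                              tests = cross$progression_tests)),
      file.path(output_dir, "cross_eval.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
      matrix = "rowmajor")
  }

  ## stage 6: subtyping
  cons <- NULL
  if (sum(diff$significant) >= 2) {
    V <- subtype_input_matrix(m, diff, clinical)
    cons <- run_stage("subtype", consensus_cluster(
      V, k_range = config$k_range, n_runs = config$n_runs,
      seed = derive_seed(config$seed, 2L)))
    write_tsv(data.frame(sample_id = names(cons$labels),
                         subtype = unname(cons$labels)),
              file.path(output_dir, "subtype_labels.tsv"))
    feat <- run_stage("subtype", suppressWarnings(
      subtype_feature_tests(cons$labels, clinical, risk$occurrence)))
    write_tsv(feat, file.path(output_dir, "subtype_feature_tests.tsv"))
    logf("stage subtype: chosen k = %d, sizes %s%s", cons$chosen_k,
         paste(table(cons$labels), collapse = "/"),
         if (cons$weak_structure) " [weak structure]" else "")
  } else logf("stage subtype: skipped (too few significant proteins)")

  summary <- list(
    n_proteins = nrow(m_raw), n_samples = ncol(m_raw),
    n_retained = nrow(m),
    n_significant = sum(diff$significant),
    identified_mean_normal = unname(counts$group_means[["normal"]]),
    identified_mean_peritumor = unname(counts$group_means[["peritumor"]]),
    occurrence_signature_size = nrow(occ_sig),
    progression_signature_size = nrow(prog_sig),
    overlap = overlap[c("n_shared", "union_size", "overlap_percent")],
    occurrence_model = if (!is.null(occ_model)) list(
      markers = occ_model$markers, auc = occ_model$train_metrics$auc,
      sensitivity = occ_model$train_metrics$sensitivity,
      specificity = occ_model$train_metrics$specificity) else NULL,
    prognostic_model = if (!is.null(prog_model)) list(
      markers = prog_model$markers,
      logrank_p = prog_model$logrank$p_value,
      roc_auc = if (!is.null(prog_model$roc)) prog_model$roc$auc else NULL) else NULL,
    chosen_k = if (!is.null(cons)) cons$chosen_k else NULL,
    subtype_sizes = if (!is.null(cons))
      as.integer(table(cons$labels)) else NULL,
    weak_structure = if (!is.null(cons)) cons$weak_structure else NULL,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  logf("pipeline complete")

  invisible(list(cohort = cohort, abundance = m, clinical = clinical,
                 counts = counts, differential = diff,
                 occurrence_signature = occ_sig,
                 progression_signature = prog_sig, overlap = overlap,
                 risk = risk, associations = assoc,
                 occurrence_model = occ_model, prognostic_model = prog_model,
                 cross_eval = cross, consensus = cons, summary = summary))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

write_model_json <- function(model, path) {
  obj <- if (inherits(model, "pme_occurrence_model")) list(
    type = "occurrence", markers = model$markers,
    coefficients = as.list(model$fit$coefficients),
    threshold = model$threshold,
    train = list(auc = model$train_metrics$auc,
                 sensitivity = model$train_metrics$sensitivity,
                 specificity = model$train_metrics$specificity))
  else list(
    type = "prognostic", markers = model$markers,
    coefficients = as.list(model$fit$coefficients),
    logrank_p = model$logrank$p_value,
    roc_auc = if (!is.null(model$roc)) model$roc$auc else NULL,
    horizon_days = model$horizon, n_excluded = model$n_excluded)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
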