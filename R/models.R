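#' Fit the three-marker occurrence model
#'
#' Logistic regression of tissue class (peritumor = 1) on the log2
#' abundances of a marker panel, with the operating threshold chosen by
#' Youden's J on the training ROC. When a validation cohort is supplied the
#' frozen coefficients (no refit) are applied to it and its ROC metrics are
#' reported alongside.
#'
#' @param m log2-scale complete [abundance_matrix()].
#' @param clinical clinical table.
#' @param markers marker protein IDs (default the HSPA4L / VIL1 / TYMP
#'   panel).
#' @param validation optional list(`abundance` = log2 matrix, `clinical` =
#'   table) for an independent cohort.
#' @return object of class `pme_occurrence_model`: `markers`, `fit`
#'   (the [logistic_fit()]), `threshold` (probability cut), `train_metrics`
#'   (a `pme_roc`), and `validation_metrics` (NULL or a list with the ROC and
#'   sensitivity/specificity at the frozen threshold).
#' @export
fit_occurrence_model <- function(m, clinical,
                                 markers = c("HSPA4L", "VIL1", "TYMP"),
                                 validation = NULL) {
  stopifnot_scale(m, "log2")
  miss <- setdiff(markers, rownames(m))
  if (length(miss)) stop("missing marker(s): ", paste(miss, collapse = ", "))
  cl <- align_clinical(m, clinical)
  y <- as.integer(cl$group == "peritumor")
  x <- t(unclass_matrix(m)[markers, , drop = FALSE])
  fit <- logistic_fit(x, y)
  train_roc <- roc_auc(fit$fitted, y)
  model <- structure(list(markers = markers, fit = fit,
                          threshold = train_roc$threshold,
                          train_metrics = train_roc,
                          validation_metrics = NULL),
                     class = "pme_occurrence_model")
  if (!is.null(validation))
    model$validation_metrics <- validate_against_cohort(
      model, validation$abundance, validation$clinical)
  model
}

#' @export
print.pme_occurrence_model <- function(x, ...) {
  cat("Occurrence model (logistic):", paste(x$markers, collapse = " + "), "\n")
  cat(sprintf("  training AUC %.3f; sens %.1f%% / spec %.1f%% at Youden threshold\n",
              x$train_metrics$auc, 100 * x$train_metrics$sensitivity,
              100 * x$train_metrics$specificity))
  if (!is.null(x$validation_metrics))
    cat(sprintf("  validation AUC %.3f; sens %.1f%% / spec %.1f%% at frozen threshold\n",
                x$validation_metrics$roc$auc,
                100 * x$validation_metrics$sensitivity,
                100 * x$validation_metrics$specificity))
  invisible(x)
}

#' @export
predict.pme_occurrence_model <- function(object, m, ...) {
  miss <- setdiff(object$markers, rownames(m))
  if (length(miss)) stop("missing marker(s): ", paste(miss, collapse = ", "))
  predict(object$fit, t(unclass_matrix(m)[object$markers, , drop = FALSE]))
}

#' Fit the three-marker prognostic model
#'
#' Cox proportional-hazards fit on the log2 abundances of a marker panel
#' over the peritumor cohort. The prognostic index (PI) is the Cox linear
#' predictor; patients are split at the median PI (values equal to the
#' median go to `low`) and the two strata are compared by Kaplan-Meier
#' curves and the log-rank test. A ROC of the PI against early death is also
#' reported: the outcome is death before the cohort's median follow-up
#' time, patients censored before that horizon are excluded (count
#' reported).
#'
#' @param m log2-scale complete [abundance_matrix()].
#' @param clinical clinical table (peritumor survival required).
#' @param markers marker panel (default CMPK2 / TYMP / NADSYN1).
#' @return object of class `pme_prognostic_model`: `markers`, `fit`
#'   (a `pme_cox`), `pi` (named per-patient PI), `pi_group`, `km`
#'   (list of `pme_km` for low/high), `logrank` (a `pme_logrank`),
#'   `roc` (PI vs early death, or NULL if degenerate), `horizon` (median
#'   follow-up, days), `n_excluded` (censored before horizon).
#' @export
fit_prognostic_model <- function(m, clinical,
                                 markers = c("CMPK2", "TYMP", "NADSYN1")) {
  stopifnot_scale(m, "log2")
  miss <- setdiff(markers, rownames(m))
  if (length(miss)) stop("missing marker(s): ", paste(miss, collapse = ", "))
  cl <- align_clinical(m, clinical)
  sv <- survival_subset(cl)
  if (sum(sv$event) < length(markers)) stop("fewer events than markers")
  x <- t(unclass_matrix(m)[markers, sv$sample_id, drop = FALSE])
  fit <- cox_fit(x, sv$survival_days, sv$event)
  pi <- stats::setNames(fit$linear_predictor, sv$sample_id)
  grp <- ifelse(pi > stats::median(pi), "high", "low")

  km <- lapply(split(seq_along(pi), grp), function(i)
    km_estimate(sv$survival_days[i], sv$event[i]))
  lr <- logrank_test(sv$survival_days, sv$event, grp)

  horizon <- stats::median(sv$survival_days)
  early <- sv$survival_days < horizon & sv$event == 1
  evaluable <- !(sv$survival_days < horizon & sv$event == 0)
  roc <- if (length(unique(early[evaluable])) == 2)
    roc_auc(pi[evaluable], as.integer(early[evaluable])) else NULL

  structure(list(markers = markers, fit = fit, pi = pi,
                 pi_group = stats::setNames(grp, sv$sample_id),
                 km = km, logrank = lr, roc = roc, horizon = horizon,
                 n_excluded = sum(!evaluable)),
            class = "pme_prognostic_model")
}

#' @export
print.pme_prognostic_model <- function(x, ...) {
  cat("Prognostic model (Cox PI):", paste(x$markers, collapse = " + "), "\n")
  cat(sprintf("  log-rank (median PI split): chi-square %.3f, p = %.4g\n",
              x$logrank$statistic, x$logrank$p_value))
  if (!is.null(x$roc))
    cat(sprintf("  PI vs death before %.0f d: AUC %.3f (%d censored excluded)\n",
                x$horizon, x$roc$auc, x$n_excluded))
  invisible(x)
}

#' @export
predict.pme_prognostic_model <- function(object, m, ...) {
  miss <- setdiff(object$markers, rownames(m))
  if (length(miss)) stop("missing marker(s): ", paste(miss, collapse = ", "))
  stats::setNames(
    drop(t(unclass_matrix(m)[object$markers, , drop = FALSE]) %*%
           coef(object$fit)),
    colnames(m))
}

#' Cross-evaluate occurrence and progression signatures
#'
#' Tests the arm-specificity claim: proteins from both signatures are
#' evaluated against both criteria — occurrence discrimination
#' (orientation-free AUC >= `auc_min`) and progression association
#' (median-split log-rank p <= `p_max`) — and arm membership is
#' cross-tabulated against each criterion in two four-fold tables with
#' chi-square and Fisher exact p-values (chi-square omitted on degenerate
#' margins).
#'
#' @param occ_sig,prog_sig non-empty `pme_signature` objects.
#' @param m log2-scale complete [abundance_matrix()].
#' @param clinical clinical table.
#' @param auc_min occurrence-discrimination threshold (default 0.8).
#' @param p_max progression-association threshold (default 0.05).
#' @return list with `occurrence_table`, `progression_table` (2x2: arm x
#'   criterion), `occurrence_tests`, `progression_tests` (chisq_p,
#'   fisher_p), and `per_protein` (data.frame of protein, arm, auc,
#'   logrank_p).
#' @export
cross_evaluate <- function(occ_sig, prog_sig, m, clinical, auc_min = 0.8,
                           p_max = 0.05) {
  if (!nrow(occ_sig) || !nrow(prog_sig)) stop("both signatures required")
  stopifnot_scale(m, "log2")
  cl <- align_clinical(m, clinical)
  lab <- as.integer(cl$group == "peritumor")
  sv <- survival_subset(cl)
  x <- unclass_matrix(m)
  xs <- x[, sv$sample_id, drop = FALSE]

  eval_one <- function(p) {
    auc <- roc_auc(x[p, ], lab)$auc
    v <- xs[p, ]
    hi <- v > stats::median(v)
    lrp <- if (length(unique(hi)) == 2)
      logrank_test(sv$survival_days, sv$event, hi)$p_value else NA_real_
    c(auc = max(auc, 1 - auc), logrank_p = lrp)
  }
  prot <- rbind(data.frame(protein_id = occ_sig$protein_id, arm = "occurrence"),
                data.frame(protein_id = prog_sig$protein_id, arm = "progression"))
  met <- t(vapply(prot$protein_id, eval_one, c(auc = 0, logrank_p = 0)))
  per_protein <- data.frame(prot, met, row.names = NULL)

  mk_tab <- function(crit) {
    tab <- table(arm = factor(per_protein$arm,
                              c("occurrence", "progression")),
                 meets = factor(crit, c(TRUE, FALSE)))
    degen <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    list(table = tab,
         tests = list(
           chisq_p = if (!degen) chi_square_test(unclass(tab))$p_value else NA_real_,
           fisher_p = fisher_exact(unclass(tab))$p_value))
  }
  occ_t <- mk_tab(per_protein$auc >= auc_min)
  prog_t <- mk_tab(!is.na(per_protein$logrank_p) & per_protein$logrank_p <= p_max)
  list(occurrence_table = occ_t$table, occurrence_tests = occ_t$tests,
       progression_table = prog_t$table, progression_tests = prog_t$tests,
       per_protein = per_protein)
}

#' Apply a frozen model to an external cohort
#'
#' Evaluates an already-fitted occurrence or prognostic model on a second
#' cohort without refitting. Occurrence models report the ROC of the frozen
#' linear predictor plus sensitivity/specificity at the frozen probability
#' threshold; prognostic models report the KM curves and log-rank test of
#' the frozen-PI median split on the new cohort.
#'
#' @param model a `pme_occurrence_model` or `pme_prognostic_model`.
#' @param m validation log2-scale [abundance_matrix()] sharing the marker
#'   IDs.
#' @param clinical validation clinical table.
#' @return metrics list (occurrence: `roc`, `sensitivity`, `specificity`,
#'   `threshold`; prognostic: `pi`, `pi_group`, `km`, `logrank`).
#' @export
validate_against_cohort <- function(model, m, clinical) {
  stopifnot_scale(m, "log2")
  cl <- align_clinical(m, clinical)
  if (inherits(model, "pme_occurrence_model")) {
    pr <- predict(model, m)
    y <- as.integer(cl$group == "peritumor")
    roc <- roc_auc(pr, y)
    pos <- pr >= model$threshold
    list(roc = roc,
         sensitivity = mean(pos[y == 1]),
         specificity = mean(!pos[y == 0]),
         threshold = model$threshold)
  } else if (inherits(model, "pme_prognostic_model")) {
    sv <- survival_subset(cl)
    pi <- predict(model, m)[sv$sample_id]
    grp <- ifelse(pi > stats::median(pi), "high", "low")
    km <- lapply(split(seq_along(pi), grp), function(i)
      km_estimate(sv$survival_days[i], sv$event[i]))
    list(pi = pi, pi_group = stats::setNames(grp, sv$sample_id), km = km,
         logrank = logrank_test(sv$survival_days, sv$event, grp))
  } else stop("unsupported model class")
}
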