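#' Select the occurrence (PME-O) signature
#'
#' Screens the significant differential proteins for normal-vs-peritumor
#' discrimination: each candidate's log2 abundance is scored by ROC AUC
#' (orientation-free, `max(auc, 1 - auc)`); proteins reaching `auc_min` are
#' retained, ranked by discriminative AUC descending (ties broken by protein
#' ID), and capped at `max_n`.
#'
#' @param diff a [differential_test()] result.
#' @param m log2-scale complete [abundance_matrix()].
#' @param clinical clinical table.
#' @param category_map named character vector protein -> functional category
#'   (six-factor scheme); unannotated proteins get `"unannotated"`.
#' @param auc_min minimum discriminative AUC (default 0.8).
#' @param max_n signature-size cap (default 40).
#' @return data.frame of class `pme_signature`: `protein_id`, `arm`,
#'   `category`, `auc`, `logrank_p` (NA for this arm), `direction`.
#' @export
select_occurrence_signature <- function(diff, m, clinical, category_map = NULL,
                                        auc_min = 0.8, max_n = 40) {
  stopifnot_scale(m, "log2")
  cl <- align_clinical(m, clinical)
  lab <- as.integer(cl$group == "peritumor")
  if (length(unique(lab)) < 2) stop("both groups required")
  cand <- diff$protein_id[diff$significant]
  cand <- intersect(cand, rownames(m))
  auc <- vapply(cand, function(p) roc_auc(unclass_matrix(m)[p, ], lab)$auc, 0)
  auc_eff <- pmax(auc, 1 - auc)
  keep <- auc_eff >= auc_min
  if (!any(keep)) {
    warning("no proteins reach auc_min; empty occurrence signature")
    return(empty_signature("occurrence"))
  }
  sig <- data.frame(protein_id = cand[keep], arm = "occurrence",
                    category = NA_character_, auc = auc_eff[keep],
                    logrank_p = NA_real_,
                    direction = ifelse(diff$log2fc[match(cand[keep], diff$protein_id)] >= 0,
                                       "up", "down"),
                    stringsAsFactors = FALSE)
  sig <- sig[order(-sig$auc, sig$protein_id), , drop = FALSE]
  sig <- utils::head(sig, max_n)
  sig$category <- map_category(sig$protein_id, category_map)
  rownames(sig) <- NULL
  class(sig) <- c("pme_signature", class(sig))
  sig
}

#' Select the progression (PME-P) signature
#'
#' For each significant differential protein, peritumor patients are split
#' at the median abundance (values equal to the median go to the low group)
#' and the two strata are compared by the log-rank test; proteins with
#' p <= `p_max` are retained, ranked by p ascending (ties by protein ID),
#' capped at `max_n`. Constant proteins (no valid split) are skipped.
#'
#' @inheritParams select_occurrence_signature
#' @param p_max log-rank p threshold (default 0.05).
#' @param max_n signature-size cap (default 52).
#' @return data.frame of class `pme_signature` (`auc` is NA for this arm;
#'   `direction` is the sign of the hazard contrast: `up` = higher abundance,
#'   shorter survival).
#' @export
select_progression_signature <- function(diff, m, clinical, category_map = NULL,
                                         p_max = 0.05, max_n = 52) {
  stopifnot_scale(m, "log2")
  cl <- align_clinical(m, clinical)
  sv <- survival_subset(cl)
  if (nrow(sv) < 2) stop("no peritumor survival data")
  if (sum(sv$event) == 0) stop("no events")
  x <- unclass_matrix(m)[, sv$sample_id, drop = FALSE]
  cand <- intersect(diff$protein_id[diff$significant], rownames(m))

  res <- lapply(cand, function(p) {
    v <- x[p, ]
    hi <- v > stats::median(v)
    if (length(unique(hi)) < 2) return(NULL)
    lr <- tryCatch(logrank_test(sv$survival_days, sv$event, hi),
                   error = function(e) NULL)
    if (is.null(lr)) return(NULL)
    ## direction: does high abundance track shorter survival?
    worse <- lr$observed["TRUE"] > lr$expected["TRUE"]
    data.frame(protein_id = p, arm = "progression", category = NA_character_,
               auc = NA_real_, logrank_p = lr$p_value,
               direction = if (isTRUE(unname(worse))) "up" else "down",
               stringsAsFactors = FALSE)
  })
  sig <- do.call(rbind, res)
  if (is.null(sig) || !any(sig$logrank_p <= p_max)) {
    warning("no proteins reach p_max; empty progression signature")
    return(empty_signature("progression"))
  }
  sig <- sig[sig$logrank_p <= p_max, , drop = FALSE]
  sig <- sig[order(sig$logrank_p, sig$protein_id), , drop = FALSE]
  sig <- utils::head(sig, max_n)
  sig$category <- map_category(sig$protein_id, category_map)
  rownames(sig) <- NULL
  class(sig) <- c("pme_signature", class(sig))
  sig
}

empty_signature <- function(arm) {
  sig <- data.frame(protein_id = character(0), arm = character(0),
                    category = character(0), auc = numeric(0),
                    logrank_p = numeric(0), direction = character(0),
                    stringsAsFactors = FALSE)
  class(sig) <- c("pme_signature", class(sig))
  sig
}

map_category <- function(ids, category_map) {
  if (is.null(category_map)) return(rep("unannotated", length(ids)))
  out <- unname(category_map[ids])
  out[is.na(out)] <- "unannotated"
  out
}

#' @export
print.pme_signature <- function(x, ...) {
  arm <- if (nrow(x)) x$arm[1] else "empty"
  cat(sprintf("PME signature (%s): %d proteins\n", arm, nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Overlap between the occurrence and progression signatures
#'
#' @param occ,prog `pme_signature` objects or character vectors of protein
#'   IDs.
#' @return list with `shared` (IDs), `n_shared`, `n_occurrence`,
#'   `n_progression`, `union_size`, and `overlap_percent`
#'   (100 * |shared| / |union|, rounded to 2 decimals).
#' @export
signature_overlap <- function(occ, prog) {
  occ_ids <- if (is.data.frame(occ)) occ$protein_id else as.character(occ)
  prog_ids <- if (is.data.frame(prog)) prog$protein_id else as.character(prog)
  shared <- intersect(occ_ids, prog_ids)
  uni <- union(occ_ids, prog_ids)
  pct <- if (length(uni)) round(100 * length(shared) / length(uni), 2) else 0
  list(shared = shared, n_shared = length(shared),
       n_occurrence = length(unique(occ_ids)),
       n_progression = length(unique(prog_ids)),
       union_size = length(uni), overlap_percent = pct)
}

#' Per-patient functional risk indices
#'
#' Aggregates a signature into per-patient, per-category risk indices (RI)
#' over the peritumor cohort. Each protein contributes `w * s` where the
#' weight `w` is `2 * (AUC - 0.5)` for the occurrence arm or
#' `min(-log10(logrank p), 4)` for the progression arm, and `s` is the
#' patient's abundance rescaled to [0, 10] across the peritumor cohort,
#' reversed (`10 - s`) for down-regulated proteins so every contribution is
#' risk-aligned. Category RIs sum the contributions of that category's
#' proteins; the total RI sums all categories; patients are split into
#' `high` / `low` at the cohort median total RI (values equal to the median
#' go to `low`).
#'
#' @param sig a non-empty `pme_signature`.
#' @param m log2-scale complete [abundance_matrix()].
#' @param clinical clinical table.
#' @return object of class `pme_risk`: list with `profiles` (data.frame:
#'   `sample_id`, one `ri_<category>` column per category, `total_ri`,
#'   `ri_group`), `summary` (range/IQR/mean of total RI), `degenerate`
#'   (TRUE when all totals are equal and the median split is meaningless),
#'   `arm`.
#' @export
compute_risk_profiles <- function(sig, m, clinical) {
  if (!nrow(sig)) stop("empty signature")
  stopifnot_scale(m, "log2")
  cl <- align_clinical(m, clinical)
  pt <- cl$sample_id[cl$group == "peritumor"]
  if (!length(pt)) stop("no peritumor samples")
  missing <- setdiff(sig$protein_id, rownames(m))
  if (length(missing))
    stop("signature proteins absent from matrix: ",
         paste(missing, collapse = ", "))
  x <- unclass_matrix(m)[sig$protein_id, pt, drop = FALSE]
  arm <- sig$arm[1]

  w <- if (arm == "occurrence") 2 * (sig$auc - 0.5)
       else pmin(-log10(pmax(sig$logrank_p, 1e-300)), 4)
  contrib <- matrix(0, nrow(sig), length(pt),
                    dimnames = list(sig$protein_id, pt))
  for (i in seq_len(nrow(sig))) {
    v <- x[i, ]
    rng <- range(v)
    s <- if (rng[2] > rng[1]) 10 * (v - rng[1]) / (rng[2] - rng[1])
         else rep(5, length(v))
    if (sig$direction[i] == "down") s <- 10 - s
    contrib[i, ] <- w[i] * s
  }

  cats <- sort(unique(sig$category))
  cat_ri <- sapply(cats, function(cc)
    colSums(contrib[sig$category == cc, , drop = FALSE]))
  cat_ri <- matrix(cat_ri, nrow = length(pt),
                   dimnames = list(pt, cats))
  total <- rowSums(cat_ri)
  med <- stats::median(total)
  degenerate <- max(total) - min(total) < 1e-12
  profiles <- data.frame(sample_id = pt, cat_ri,
                         total_ri = unname(total),
                         ri_group = ifelse(total > med, "high", "low"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(profiles)[seq_along(cats) + 1] <- paste0("ri_", cats)
  rownames(profiles) <- NULL
  structure(list(profiles = profiles,
                 summary = c(min = min(total), max = max(total),
                             q1 = unname(stats::quantile(total, 0.25)),
                             q3 = unname(stats::quantile(total, 0.75)),
                             mean = mean(total), median = med),
                 degenerate = degenerate, arm = arm),
            class = "pme_risk")
}

#' @export
print.pme_risk <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Risk profiles (%s arm): %d patients; total RI %.2f-%.2f (IQR %.2f~%.2f; mean %.2f)\n",
              x$arm, nrow(x$profiles), s["min"], s["max"], s["q1"], s["q3"],
              s["mean"]))
  if (x$degenerate) cat("  [degenerate: all patients share one RI]\n")
  invisible(x)
}

#' Association between RI group and a dichotomized clinical covariate
#'
#' Cross-tabulates the high/low RI split against `covariate > cutoff` and
#' reports both the Pearson chi-square and Fisher exact p. Samples with a
#' missing covariate are dropped pairwise and counted.
#'
#' @param risk a [compute_risk_profiles()] result.
#' @param clinical clinical table.
#' @param covariate clinical column name (e.g. `afp_ng_ml` with cutoff 300,
#'   `cyp2e1_activity` with cutoff 1350, `survival_days` with cutoff 344).
#' @param cutoff dichotomization threshold (strictly-greater rule).
#' @return list with `table` (2x2: RI group x covariate high), `chisq_p`,
#'   `fisher_p`, `n_missing`, `degenerate` (zero margin; chi-square skipped).
#' @export
ri_clinical_association <- function(risk, clinical, covariate, cutoff) {
  prof <- risk$profiles
  if (!covariate %in% names(clinical)) stop("unknown covariate: ", covariate)
  v <- clinical[[covariate]][match(prof$sample_id, clinical$sample_id)]
  ok <- !is.na(v)
  n_missing <- sum(!ok)
  g <- factor(prof$ri_group[ok], levels = c("low", "high"))
  hi <- factor(v[ok] > cutoff, levels = c(FALSE, TRUE))
  tab <- table(ri_group = g, covariate_high = hi)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  chisq_p <- if (!degenerate) chi_square_test(unclass(tab))$p_value else NA_real_
  list(table = tab, chisq_p = chisq_p,
       fisher_p = fisher_exact(unclass(tab))$p_value,
       n_missing = n_missing, degenerate = degenerate)
}

#' Compare risk indices across functional categories
#'
#' Per-category mean and median RI across patients, an omnibus
#' Kruskal-Wallis test across categories, and Bonferroni-adjusted pairwise
#' Wilcoxon rank-sum tests. Categories are reported in descending mean-RI
#' order.
#'
#' @param risk a [compute_risk_profiles()] result with >= 2 categories.
#' @return list with `summary` (data.frame: category, mean, median ordered by
#'   descending mean), `kruskal_p` (NA when only one category), `pairwise`
#'   (matrix of adjusted p-values, or NULL).
#' @export
compare_category_ri <- function(risk) {
  prof <- risk$profiles
  cats <- setdiff(grep("^ri_", names(prof), value = TRUE), "ri_group")
  long <- data.frame(
    category = rep(sub("^ri_", "", cats), each = nrow(prof)),
    ri = unlist(prof[cats], use.names = FALSE))
  smry <- do.call(rbind, lapply(split(long$ri, long$category), function(v)
    data.frame(mean = mean(v), median = stats::median(v))))
  smry <- data.frame(category = rownames(smry), smry, row.names = NULL)
  smry <- smry[order(-smry$mean), ]
  if (length(cats) < 2)
    return(list(summary = smry, kruskal_p = NA_real_, pairwise = NULL))
  kw <- stats::kruskal.test(ri ~ factor(category), data = long)
  pw <- stats::pairwise.wilcox.test(long$ri, factor(long$category),
                                    p.adjust.method = "bonferroni",
                                    exact = FALSE)
  list(summary = smry, kruskal_p = kw$p.value, pairwise = pw$p.value)
}
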