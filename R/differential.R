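#' Per-sample identified-protein counts
#'
#' Counts non-missing proteins per sample on the raw (pre-imputation) matrix
#' and compares the two groups by a two-sample Student's t test.
#'
#' @param m linear-scale [abundance_matrix()] with missingness intact.
#' @param clinical clinical table (see [read_clinical()]).
#' @return list with `counts` (data.frame: sample_id, group, n_identified),
#'   `group_means`, and `p_value`.
#' @export
count_identified <- function(m, clinical) {
  cl <- align_clinical(m, clinical)
  n_id <- colSums(!is.na(m))
  if (min(table(factor(cl$group, c("normal", "peritumor")))) == 0L)
    stop("both groups required")
  p <- tryCatch(stats::t.test(n_id[cl$group == "peritumor"],
                              n_id[cl$group == "normal"],
                              var.equal = TRUE)$p.value,
                error = function(e) NA_real_)  # constant counts
  list(counts = data.frame(sample_id = cl$sample_id, group = cl$group,
                           n_identified = unname(n_id)),
       group_means = tapply(n_id, cl$group, mean),
       p_value = p)
}

#' Two-group differential expression
#'
#' Per-protein normal-vs-peritumor comparison on the preprocessed log2
#' matrix. `method = "student"` is the equal-variance two-sample t test;
#' `method = "moderated"` is the empirical-Bayes variance-shrunk t (limma).
#' The fold change is the linear-scale ratio of group means
#' (peritumor / normal), and a protein is called significant when the fold
#' change exceeds `fc_threshold` in either direction (> fc or < 1/fc) and
#' p < `p_threshold`. No multiple-testing correction is applied by default
#' (the screening rule is a raw p cutoff); Benjamini-Hochberg is available
#' via `adjust = "BH"`, in which case the adjusted p is thresholded.
#'
#' @param m log2-scale, complete [abundance_matrix()].
#' @param clinical clinical table.
#' @param method `"student"` or `"moderated"`.
#' @param fc_threshold linear fold-change threshold (default 1.2).
#' @param p_threshold p-value threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of class `pme_differential`: `protein_id`, `log2fc`,
#'   `fold_change`, `p_value`, (`p_adjust`,) `direction` (`up`/`down`),
#'   `significant`, `zero_variance` flag.
#' @export
differential_test <- function(m, clinical, method = c("student", "moderated"),
                              fc_threshold = 1.2, p_threshold = 0.05,
                              adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot_scale(m, "log2")
  if (anyNA(m)) stop("differential test expects a complete (imputed) matrix")
  cl <- align_clinical(m, clinical)
  pt <- cl$group == "peritumor"
  if (sum(pt) < 2 || sum(!pt) < 2) stop("need >= 2 samples per group")
  x <- unclass_matrix(m)

  ## linear-scale group means for the fold change
  lin <- 2^x
  fc <- rowMeans(lin[, pt, drop = FALSE]) / rowMeans(lin[, !pt, drop = FALSE])
  log2fc <- log2(fc)

  if (method == "student") {
    n1 <- sum(pt); n0 <- sum(!pt)
    m1 <- rowMeans(x[, pt, drop = FALSE]); m0 <- rowMeans(x[, !pt, drop = FALSE])
    v1 <- apply(x[, pt, drop = FALSE], 1, stats::var)
    v0 <- apply(x[, !pt, drop = FALSE], 1, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    zero_var <- sp2 <= 0
    tt <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    p <- 2 * stats::pt(-abs(tt), df = n1 + n0 - 2)
    p[zero_var] <- 1
  } else {
    design <- cbind(Intercept = 1, peritumor = as.numeric(pt))
    fit <- limma::eBayes(limma::lmFit(x, design))
    p <- fit$p.value[, "peritumor"]
    zero_var <- fit$sigma == 0
    p[zero_var] <- 1
  }

  out <- data.frame(protein_id = rownames(m), log2fc = unname(log2fc),
                    fold_change = unname(fc), p_value = unname(p),
                    stringsAsFactors = FALSE)
  p_eff <- out$p_value
  if (adjust == "BH") {
    out$p_adjust <- stats::p.adjust(out$p_value, "BH")
    p_eff <- out$p_adjust
  }
  out$direction <- ifelse(out$log2fc >= 0, "up", "down")
  out$significant <- (out$fold_change > fc_threshold |
                        out$fold_change < 1 / fc_threshold) &
    p_eff < p_threshold & !zero_var
  out$zero_variance <- unname(zero_var)
  class(out) <- c("pme_differential", class(out))
  attr(out, "method") <- method
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Volcano-plot table
#'
#' One row per protein: effect size (log2 fold change), -log10 p, and the
#' significance call. No filtering.
#'
#' @param records a [differential_test()] result.
#' @return data.frame with `protein_id`, `log2fc`, `neg_log10_p`,
#'   `significant`.
#' @export
volcano_table <- function(records) {
  data.frame(protein_id = records$protein_id, log2fc = records$log2fc,
             neg_log10_p = -log10(pmax(records$p_value, 1e-300)),
             significant = records$significant, stringsAsFactors = FALSE)
}
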