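#' Non-negative matrix factorization
#'
#' Rank-k factorization V ~ W H by multiplicative updates, minimizing the
#' Frobenius reconstruction error (default) or generalized Kullback-Leibler
#' divergence. W and H are initialized uniform(0, 1] scaled so the initial
#' product matches the mean of V; iteration stops when the relative change
#' of the objective falls below `tol` or after `max_iter` iterations. The
#' result is a deterministic function of (V, k, seed).
#'
#' @param V non-negative numeric matrix, no missing values.
#' @param k factorization rank, `k < min(dim(V))`.
#' @param seed RNG seed for the initialization.
#' @param objective `"frobenius"` or `"kl"`.
#' @param max_iter iteration cap (default 2000).
#' @param tol relative objective-change tolerance (default 1e-6).
#' @return list with `W` (rows x k), `H` (k x cols), `error` (final
#'   objective), `error_trace`, `iterations`, `converged`.
#' @export
nmf_factorize <- function(V, k, seed = 1, objective = c("frobenius", "kl"),
                          max_iter = 2000, tol = 1e-6) {
  objective <- match.arg(objective)
  V <- as.matrix(V)
  if (anyNA(V)) stop("missing values not allowed")
  if (any(V < 0)) stop("negative entries not allowed")
  if (k >= min(dim(V)) || k < 1) stop("k must satisfy 1 <= k < min(dim(V))")
  n <- nrow(V); p <- ncol(V)
  eps <- .Machine$double.eps

  with_seed(seed, {
    ## W is seeded uniform(0,1]-scaled; H starts from the row-scaled
    ## projection of V onto W, so a column permutation of V permutes the
    ## whole run (init included) and consensus matrices are permutation-
    ## equivariant
    sc <- sqrt(max(mean(V), eps) / k)
    W <- matrix(sc * stats::runif(n * k), n, k)
    H <- sweep(crossprod(W, V), 1, colSums(W^2) + eps, "/")
    obj <- function(W, H) {
      R <- W %*% H
      if (objective == "frobenius") sum((V - R)^2)
      else sum(V * log((V + eps) / (R + eps)) - V + R)
    }
    err <- obj(W, H)
    trace <- err
    converged <- FALSE
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      if (objective == "frobenius") {
        H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
        W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      } else {
        R <- W %*% H + eps
        H <- H * (crossprod(W, V / R)) / (colSums(W) + eps)
        R <- W %*% H + eps
        W <- W * ((V / R) %*% t(H)) / matrix(rowSums(H) + eps, n, k,
                                             byrow = TRUE)
      }
      new_err <- obj(W, H)
      trace <- c(trace, new_err)
      if (abs(err - new_err) < tol * max(err, eps)) {
        err <- new_err; converged <- TRUE; break
      }
      err <- new_err
    }
    list(W = W, H = H, error = err, error_trace = trace, iterations = it,
         converged = converged)
  })
}

#' NMF consensus clustering
#'
#' Repeated seeded NMF restarts per candidate rank; each run assigns every
#' sample (column) to its argmax basis component, and the consensus matrix
#' records the co-assignment frequency over runs. Per rank the cophenetic
#' correlation (between the consensus dissimilarity and the average-linkage
#' tree built from it), the dispersion `mean((2C - 1)^2)`, and the area
#' under the consensus CDF are computed; the chosen rank maximizes the
#' cophenetic coefficient, and final labels come from cutting the
#' average-linkage tree of `1 - consensus` at that rank. A `weak_structure`
#' flag is raised when even the best rank shows unstable co-assignment
#' (cophenetic < 0.95 or dispersion < 0.5), as happens on structure-free
#' input where consensus entries hover near the cluster-proportion
#' baseline.
#'
#' @param V non-negative matrix (features x samples), e.g. the significant
#'   differential proteins over peritumor samples shifted non-negative.
#' @param k_range candidate ranks (default 2:6).
#' @param n_runs NMF restarts per rank (default 50).
#' @param seed master seed; run seeds are derived deterministically.
#' @param ... passed to [nmf_factorize()] (objective, max_iter, tol).
#' @return object of class `pme_consensus`: `k_range`, `consensus` (list of
#'   sample x sample matrices), `cophenetic`, `dispersion`, `cdf_area`,
#'   `delta_cdf_area`, `best_error` (per rank, best restart), `chosen_k`,
#'   `labels` (named subtype per sample), `weak_structure`, `n_runs`,
#'   `seed`.
#' @export
consensus_cluster <- function(V, k_range = 2:6, n_runs = 50, seed = 1, ...) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("negative entries not allowed")
  ns <- ncol(V)
  if (min(k_range) < 2 || max(k_range) >= min(dim(V)))
    stop("k_range outside valid bounds")
  consensus <- list(); coph <- disp <- area <- best_err <- numeric(0)
  for (k in k_range) {
    C <- matrix(0, ns, ns)
    kerr <- Inf
    for (r in seq_len(n_runs)) {
      run_seed <- derive_seed(seed, k * 1000L + r)
      f <- nmf_factorize(V, k, seed = run_seed, ...)
      lab <- apply(f$H, 2, which.max)
      C <- C + outer(lab, lab, "==")
      kerr <- min(kerr, f$error)
    }
    C <- C / n_runs
    dimnames(C) <- list(colnames(V), colnames(V))
    d <- stats::as.dist(1 - C)
    hc <- stats::hclust(d, method = "average")
    cc <- if (stats::sd(d) > 0)
      stats::cor(d, stats::cophenetic(hc)) else 1
    kk <- as.character(k)
    consensus[[kk]] <- C
    coph[kk] <- cc
    disp[kk] <- mean((2 * C - 1)^2)
    area[kk] <- consensus_cdf_area(C)
    best_err[kk] <- kerr
  }
  chosen_k <- k_range[which.max(coph)]
  Cbest <- consensus[[as.character(chosen_k)]]
  hc <- stats::hclust(stats::as.dist(1 - Cbest), method = "average")
  labels <- stats::cutree(hc, k = chosen_k)
  names(labels) <- colnames(V)
  weak <- coph[as.character(chosen_k)] < 0.95 ||
    disp[as.character(chosen_k)] < 0.5
  structure(list(k_range = k_range, consensus = consensus,
                 cophenetic = coph, dispersion = disp, cdf_area = area,
                 delta_cdf_area = c(NA, diff(area)),
                 best_error = best_err, chosen_k = chosen_k,
                 labels = labels, weak_structure = unname(weak),
                 n_runs = n_runs, seed = seed),
            class = "pme_consensus")
}

## area under the empirical CDF of the off-diagonal consensus entries
consensus_cdf_area <- function(C) {
  v <- sort(C[upper.tri(C)])
  if (!length(v)) return(NA_real_)
  ## integral over [0,1] of the ECDF: sum of widths x heights
  xs <- c(0, v, 1)
  heights <- c(0, seq_along(v) / length(v))
  sum(diff(xs) * heights)
}

#' @export
print.pme_consensus <- function(x, ...) {
  cat(sprintf("NMF consensus clustering: k in {%s}, %d runs each\n",
              paste(x$k_range, collapse = ","), x$n_runs))
  tab <- data.frame(k = x$k_range, cophenetic = round(x$cophenetic, 4),
                    dispersion = round(x$dispersion, 4),
                    cdf_area = round(x$cdf_area, 4))
  print(tab, row.names = FALSE)
  cat(sprintf("  chosen k = %d (max cophenetic); subtype sizes: %s%s\n",
              x$chosen_k, paste(table(x$labels), collapse = "/"),
              if (x$weak_structure) "  [weak structure]" else ""))
  invisible(x)
}

#' Subtype-feature association tests
#'
#' Compares clinical and risk features across consensus subtypes. Numeric
#' features use one-way ANOVA when a Brown-Forsythe check (Levene on median
#' deviations) finds homogeneous variances (p > 0.05), otherwise
#' Kruskal-Wallis; categorical features use the Pearson chi-square test.
#' Subtypes with fewer than 2 samples are dropped with a warning.
#'
#' @param labels named subtype labels (from [consensus_cluster()]).
#' @param clinical clinical table.
#' @param risk optional [compute_risk_profiles()] result whose per-category
#'   RIs are tested too.
#' @param features clinical columns to test; defaults to survival days,
#'   CYP2E1 activity (numeric) and cirrhosis stage, tumor multiplicity
#'   (categorical).
#' @return data.frame: `feature`, `test` (`anova`/`kruskal`/`chisq`),
#'   `statistic`, `p_value`, and per-subtype means for numeric features.
#' @export
subtype_feature_tests <- function(labels, clinical, risk = NULL,
                                  features = NULL) {
  if (is.null(features))
    features <- c("survival_days", "cyp2e1_activity", "cirrhosis_stage",
                  "tumor_multiplicity")
  keep_lab <- names(table(labels))[table(labels) >= 2]
  if (length(keep_lab) < length(unique(labels)))
    warning("subtype(s) with < 2 samples excluded")
  labels <- labels[as.character(labels) %in% keep_lab]
  if (length(unique(labels)) < 2) stop("need >= 2 subtypes")
  g <- factor(labels)

  dat <- clinical[match(names(labels), clinical$sample_id), , drop = FALSE]
  numeric_feats <- intersect(features, names(dat))
  numeric_feats <- numeric_feats[vapply(dat[numeric_feats], function(v)
    length(unique(stats::na.omit(v))) > 5, TRUE)]
  cat_feats <- setdiff(intersect(features, names(dat)), numeric_feats)

  blocks <- lapply(numeric_feats, function(f)
    test_numeric_feature(dat[[f]], g, f))
  if (!is.null(risk)) {
    prof <- risk$profiles[match(names(labels), risk$profiles$sample_id), ]
    ri_cols <- setdiff(grep("^ri_", names(prof), value = TRUE), "ri_group")
    for (f in c(ri_cols, "total_ri"))
      blocks <- c(blocks, list(test_numeric_feature(prof[[f]], g, f)))
  }
  for (f in cat_feats) {
    v <- dat[[f]]
    ok <- !is.na(v)
    tab <- table(g[ok], v[ok])
    res <- tryCatch(chi_square_test(unclass(tab)),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_))
    blocks <- c(blocks, list(data.frame(feature = f, test = "chisq",
                                        statistic = res$statistic,
                                        p_value = res$p_value)))
  }
  all_cols <- Reduce(union, lapply(blocks, names))
  out <- do.call(rbind, lapply(blocks, function(b) {
    b[setdiff(all_cols, names(b))] <- NA
    b[all_cols]
  }))
  rownames(out) <- NULL
  out
}

test_numeric_feature <- function(v, g, name) {
  ok <- !is.na(v)
  v <- v[ok]; gg <- droplevels(g[ok])
  if (length(unique(gg)) < 2 || length(v) < 4)
    return(data.frame(feature = name, test = "none", statistic = NA_real_,
                      p_value = NA_real_))
  ## Brown-Forsythe variance check on absolute deviations from group medians
  med <- tapply(v, gg, stats::median)
  dev <- abs(v - med[as.character(gg)])
  lev_p <- tryCatch(stats::anova(stats::lm(dev ~ gg))$`Pr(>F)`[1],
                    error = function(e) 0)
  if (!is.na(lev_p) && lev_p > 0.05) {
    a <- stats::anova(stats::lm(v ~ gg))
    res <- data.frame(feature = name, test = "anova",
                      statistic = a$`F value`[1], p_value = a$`Pr(>F)`[1])
  } else {
    k <- stats::kruskal.test(v, gg)
    res <- data.frame(feature = name, test = "kruskal",
                      statistic = unname(k$statistic), p_value = k$p.value)
  }
  mns <- tapply(v, gg, mean)
  for (lv in names(mns)) res[[paste0("mean_", lv)]] <- mns[[lv]]
  res
}

#' Prepare a matrix for NMF subtyping
#'
#' Restricts the preprocessed log2 matrix to the significant differential
#' proteins and the peritumor samples and shifts it by its global minimum so
#' all entries are non-negative (NMF requires a non-negative input).
#'
#' @param m log2-scale complete [abundance_matrix()].
#' @param diff a [differential_test()] result.
#' @param clinical clinical table.
#' @return plain non-negative matrix, significant proteins x peritumor
#'   samples.
#' @export
subtype_input_matrix <- function(m, diff, clinical) {
  stopifnot_scale(m, "log2")
  cl <- align_clinical(m, clinical)
  sig <- intersect(diff$protein_id[diff$significant], rownames(m))
  if (length(sig) < 2) stop("too few significant proteins for subtyping")
  x <- unclass_matrix(m)[sig, cl$sample_id[cl$group == "peritumor"],
                         drop = FALSE]
  x - min(x)
}
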