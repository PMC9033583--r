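#' Detection filtering
#'
#' Drops proteins detected (non-missing) in fewer than `min_frac` of all
#' samples; a protein observed in exactly `min_frac` of samples is kept
#' (the exclusion rule is "detected in < min_frac"). Row order is preserved.
#'
#' @param m linear-scale [abundance_matrix()] with missingness intact.
#' @param min_frac minimum detection fraction in (0, 1]; default 0.5.
#' @return filtered abundance matrix.
#' @export
filter_by_detection <- function(m, min_frac = 0.5) {
  stopifnot_scale(m, "linear")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  frac <- rowMeans(!is.na(m))
  keep <- frac >= min_frac - 1e-12
  if (!any(keep)) warning("no proteins pass the detection filter")
  m[keep, , drop = FALSE]
}

#' Half-minimum imputation
#'
#' Replaces each missing value of a protein with half that protein's minimum
#' observed intensity — the conventional stand-in for values left-censored
#' at the detection limit. Observed cells are untouched. A protein with no
#' observed value at all is an error (it should have been filtered).
#'
#' @param m linear-scale [abundance_matrix()].
#' @return complete abundance matrix.
#' @export
impute_half_min <- function(m) {
  stopifnot_scale(m, "linear")
  miss <- is.na(m)
  if (!any(miss)) return(m)
  nobs <- rowSums(!miss)
  if (any(nobs == 0))
    stop("all-missing protein row(s): ",
         paste(utils::head(rownames(m)[nobs == 0], 5), collapse = ", "))
  rmin <- apply(m, 1, min, na.rm = TRUE)
  out <- unclass_matrix(m)
  idx <- which(miss, arr.ind = TRUE)
  out[idx] <- rmin[idx[, 1]] / 2
  as_abundance(out, abn_scale(m))
}

#' Quantile normalization
#'
#' Forces every sample (column) to the same empirical distribution: the
#' across-sample mean of order statistics. Within a column, tied values
#' receive the mean of their target quantiles (midrank interpolation), so
#' within-column rank order is preserved. A single-column matrix is returned
#' unchanged.
#'
#' @param m complete (post-imputation) [abundance_matrix()].
#' @return normalized abundance matrix on the same scale.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stop("quantile normalization requires a complete matrix")
  if (ncol(m) < 2) return(m)
  v <- unclass_matrix(m)
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(v)
  as_abundance(out, abn_scale(m))
}

#' Log2 transformation
#'
#' Elementwise log2 of a strictly positive linear-scale matrix; flips the
#' scale flag to `"log2"`.
#'
#' @param m linear-scale, strictly positive [abundance_matrix()].
#' @return log2-scale abundance matrix.
#' @export
log2_transform <- function(m) {
  stopifnot_scale(m, "linear")
  if (any(m <= 0, na.rm = TRUE)) stop("values must be strictly positive")
  as_abundance(log2(unclass_matrix(m)), "log2")
}

#' Standard preprocessing pipeline
#'
#' filter (detection >= `min_detect`) -> half-minimum imputation ->
#' quantile normalization (optional) -> log2. Imputation precedes
#' normalization because the half-minimum rule needs per-protein minima on
#' the raw linear scale, and quantile normalization assumes complete data.
#'
#' @param m linear-scale [abundance_matrix()] with missingness intact.
#' @param min_detect detection-fraction threshold (default 0.5).
#' @param quantile apply quantile normalization (default TRUE).
#' @return log2-scale, complete, normalized abundance matrix.
#' @export
preprocess_abundance <- function(m, min_detect = 0.5, quantile = TRUE) {
  m <- filter_by_detection(m, min_detect)
  m <- impute_half_min(m)
  if (quantile) m <- quantile_normalize(m)
  log2_transform(m)
}
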