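#' Construct an abundance matrix
#'
#' Container for a protein-by-sample intensity matrix (iBAQ-like, non-negative
#' on the linear scale) with missing values allowed. Rows are proteins,
#' columns are samples; the object is an ordinary numeric matrix carrying a
#' `scale` attribute (`"linear"` or `"log2"`) so downstream operations can
#' refuse inputs on the wrong scale.
#'
#' @param values numeric matrix, proteins x samples, with rownames (protein
#'   IDs) and colnames (sample IDs). `NA` marks a non-detected value.
#' @param scale `"linear"` (raw intensities, non-negative) or `"log2"`.
#' @return an `abundance_matrix` object.
#' @export
abundance_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("protein IDs must be unique")
  if (anyDuplicated(colnames(values)))
    stop("sample IDs must be unique")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop("negative intensities on the linear scale")
  structure(values, scale = scale, class = c("abundance_matrix", class(values)))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d proteins x %d samples [%s scale], %.1f%% missing\n",
              nrow(x), ncol(x), abn_scale(x), 100 * mean(is.na(x))))
  invisible(x)
}

abn_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) "linear" else s
}

as_abundance <- function(m, scale) {
  abundance_matrix(unclass_matrix(m), scale = scale)
}

unclass_matrix <- function(m) {
  attr(m, "scale") <- NULL
  class(m) <- setdiff(class(m), "abundance_matrix")
  m
}

## subsetting keeps the scale attribute (and class) when the result is a matrix
#' @export
`[.abundance_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale = abn_scale(x),
                     class = c("abundance_matrix", class(out)))
  out
}

stopifnot_scale <- function(m, scale) {
  if (!identical(abn_scale(m), scale))
    stop(sprintf("expected an abundance matrix on the %s scale, got %s",
                 scale, abn_scale(m)))
}

## deterministic RNG scoping: run expr under a seed, restore global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## stable sub-seed derivation so pipeline stages are independently reproducible
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647L)
}
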