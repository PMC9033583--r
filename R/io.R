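#' Read / write the abundance TSV dialect
#'
#' Tab-separated, proteins as rows; first column `protein_id`, remaining
#' header fields are sample IDs; an empty cell is a missing (non-detected)
#' value. Values are linear-scale intensities.
#'
#' @param path file path.
#' @return [abundance_matrix()] on the linear scale.
#' @export
read_abundance <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = NA, na.strings = "", quote = "",
                          comment.char = "")
  if (names(df)[1] != "protein_id") stop("first column must be 'protein_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein_id
  abundance_matrix(m, "linear")
}

#' @param m an [abundance_matrix()] on the linear scale.
#' @rdname read_abundance
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(protein_id = rownames(m), unclass_matrix(m),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write the clinical CSV
#'
#' One row per sample. Columns: `sample_id`; `group` (`normal` or
#' `peritumor`); `survival_days` (overall survival, days; NA for normal
#' tissue donors); `event` (1 = death observed, 0 = censored);
#' `afp_ng_ml` (serum alpha-fetoprotein, ng/mL); `cirrhosis_stage`
#' (ordinal 0-4); `cyp2e1_activity` (liver microsomal CYP2E1 activity,
#' pmol/min/mg protein); `tumor_diameter_cm`; `tumor_multiplicity`
#' (0 = single, 1 = multiple).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
  df
}

#' @param clinical clinical data.frame as documented above.
#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_clinical <- function(df) {
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$group %in% c("normal", "peritumor")))
    stop("group must be 'normal' or 'peritumor'")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs")
  invisible(df)
}

## align a clinical table to the columns of an abundance matrix
align_clinical <- function(m, clinical) {
  validate_clinical(clinical)
  idx <- match(colnames(m), clinical$sample_id)
  if (anyNA(idx))
    stop("samples absent from clinical table: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  clinical[idx, , drop = FALSE]
}

## peritumor samples that carry usable survival data
survival_subset <- function(clinical) {
  keep <- clinical$group == "peritumor" & !is.na(clinical$survival_days) &
    !is.na(clinical$event)
  cl <- clinical[keep, , drop = FALSE]
  if (any(cl$survival_days <= 0)) stop("survival times must be positive")
  if (!all(cl$event %in% c(0, 1))) stop("event must be 0/1")
  cl
}
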