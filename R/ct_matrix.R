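## Data model and CSV I/O for Ct matrices, sample sheets and assay sheets.
##
## A Ct matrix is stored as a plain numeric matrix (rows = samples,
## columns = assays) of threshold-cycle values, with NA encoding an
## undetected ("Undetermined") well. Undetected wells are missing data
## throughout the pipeline: they are never imputed with a ceiling Ct.

ASSAY_ROLES      <- c("target", "housekeeping", "reference-candidate")
ASSAY_CATEGORIES <- c("CD-locus", "Th17", "both", "none")

#' Construct and validate a Ct matrix
#'
#' @param x numeric matrix of Ct values (cycles); rows are samples, columns
#'   are assays. `NA` marks an undetected well.
#' @return the validated matrix with class `ct_matrix` prepended.
#' @export
ct_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    ct_format_error("Ct matrix must be a numeric matrix (samples x assays)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    ct_format_error("Ct matrix requires sample row names and assay column names")
  if (anyDuplicated(rownames(x)))
    ct_format_error("duplicate sample ids in Ct matrix")
  if (anyDuplicated(colnames(x)))
    ct_format_error("duplicate assay ids in Ct matrix")
  if (any(x[!is.na(x)] <= 0))
    ct_format_error("all numeric Ct values must be > 0 cycles")
  class(x) <- c("ct_matrix", class(unclass(x)))
  x
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d samples x %d assays, %d undetected wells (%.1f%%)\n",
              nrow(x), ncol(x), sum(is.na(x)),
              100 * mean(is.na(x))))
  invisible(x)
}

#' Read a wide-format Ct matrix from CSV
#'
#' The expected dialect mirrors TaqMan array card exports: a header row of
#' assay ids, one row per sample with the sample id in the first column,
#' and undetected wells carrying a sentinel token (default `"Undetermined"`).
#'
#' @param path CSV file path.
#' @param sentinel token marking an undetected well.
#' @return a [ct_matrix()].
#' @export
read_ct_table <- function(path, sentinel = "Undetermined") {
  if (!file.exists(path)) ct_input_error(paste0("file not found: ", path))
  raw <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) ct_format_error("Ct CSV needs a sample-id column plus assay columns")
  ids <- raw[[1]]
  assays <- colnames(raw)[-1]
  if (anyDuplicated(ids))
    ct_format_error(paste0("duplicate sample id in ", path, ": ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (anyDuplicated(assays))
    ct_format_error(paste0("duplicate assay column in ", path, ": ",
                           paste(unique(assays[duplicated(assays)]), collapse = ", ")))
  m <- matrix(NA_real_, nrow(raw), length(assays),
              dimnames = list(ids, assays))
  for (j in seq_along(assays)) {
    cell <- trimws(raw[[j + 1L]])
    und <- cell == sentinel | cell == "" | is.na(cell)
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!und & is.na(val))
    if (length(bad))
      ct_format_error(sprintf(
        "non-numeric Ct value '%s' at sample '%s', assay '%s'",
        cell[bad[1]], ids[bad[1]], assays[j]))
    val[und] <- NA_real_
    m[, j] <- val
  }
  ct_matrix(m)
}

#' Write a Ct matrix as wide CSV
#'
#' Inverse of [read_ct_table()]: undetected wells are written as the
#' sentinel token.
#'
#' @inheritParams read_ct_table
#' @param ct a [ct_matrix()].
#' @export
write_ct_table <- function(ct, path, sentinel = "Undetermined") {
  out <- as.data.frame(formatC(unclass(ct), format = "fg", digits = 15),
                       stringsAsFactors = FALSE, check.names = FALSE)
  out[is.na(unclass(ct))] <- sentinel
  out <- cbind(sample_id = rownames(ct), out)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Columns: `sample_id`, `age_years` (positive), `age_group`
#' (`child`/`adult`), `status` (`CD`/`control`).
#'
#' @param path CSV file path.
#' @param ct optional [ct_matrix()] whose sample ids must match.
#' @return validated data frame.
#' @export
read_sample_table <- function(path, ct = NULL) {
  if (!file.exists(path)) ct_input_error(paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(df, ct)
}

#' @rdname read_sample_table
#' @param samples sample sheet data frame.
#' @export
validate_sample_table <- function(samples, ct = NULL) {
  need <- c("sample_id", "age_years", "age_group", "status")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    ct_format_error(paste0("sample sheet missing column(s): ",
                           paste(miss, collapse = ", ")))
  if (anyDuplicated(samples$sample_id))
    ct_format_error("duplicate sample ids in sample sheet")
  if (any(is.na(samples$age_group)) || any(is.na(samples$status)))
    ct_format_error("age_group and status must be non-missing")
  if (!all(samples$age_group %in% c("child", "adult")))
    ct_format_error("age_group must be 'child' or 'adult'")
  if (!all(samples$status %in% c("CD", "control")))
    ct_format_error("status must be 'CD' or 'control'")
  if (any(!is.na(samples$age_years) & samples$age_years <= 0))
    ct_format_error("age_years must be positive")
  if (!is.null(ct) && !setequal(samples$sample_id, rownames(ct)))
    ct_format_error("sample sheet ids do not match Ct matrix sample ids")
  samples
}

#' Read and validate an assay sheet
#'
#' Columns: `assay_id` (TaqMan-style, e.g. `Hs01073297_m1`), `gene`,
#' `role` (`target`, `housekeeping`, `reference-candidate`) and `category`
#' (`CD-locus`, `Th17`, `both`, `none`).
#'
#' @param path CSV file path.
#' @param ct optional [ct_matrix()]; one sheet row per matrix assay required.
#' @return validated data frame.
#' @export
read_assay_table <- function(path, ct = NULL) {
  if (!file.exists(path)) ct_input_error(paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_assay_table(df, ct)
}

#' @rdname read_assay_table
#' @param assays assay sheet data frame.
#' @export
validate_assay_table <- function(assays, ct = NULL) {
  need <- c("assay_id", "gene", "role")
  miss <- setdiff(need, names(assays))
  if (length(miss))
    ct_format_error(paste0("assay sheet missing column(s): ",
                           paste(miss, collapse = ", ")))
  if (is.null(assays$category)) assays$category <- "none"
  if (anyDuplicated(assays$assay_id))
    ct_format_error("duplicate assay ids in assay sheet")
  if (!all(assays$role %in% ASSAY_ROLES))
    ct_format_error(paste0("assay role must be one of: ",
                           paste(ASSAY_ROLES, collapse = ", ")))
  if (!all(assays$category %in% ASSAY_CATEGORIES))
    ct_format_error(paste0("assay category must be one of: ",
                           paste(ASSAY_CATEGORIES, collapse = ", ")))
  if (!is.null(ct) && !setequal(assays$assay_id, colnames(ct)))
    ct_format_error("assay sheet ids do not match Ct matrix assay ids")
  assays
}
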