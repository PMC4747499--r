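## Detection-based filtering and comparative-Ct quantification.

#' Partition assays by detection status
#'
#' Non-housekeeping assays (roles `target` and `reference-candidate`) are
#' split into three disjoint groups: `all_undetected` (detected in zero
#' samples), `majority_undetected` (detected in more than zero but fewer
#' than `majority_fraction` of all samples, strictly) and `analyzable`.
#' Only analyzable assays enter stability ranking and differential testing.
#'
#' @param ct a [ct_matrix()].
#' @param assays assay sheet (see [read_assay_table()]); only its
#'   `target`/`reference-candidate` rows are partitioned.
#' @param majority_fraction detection fraction below which an assay is
#'   discarded as majority-undetected (default 0.5, i.e. "detected in a
#'   minority of samples").
#' @return list of class `detection_partition` with character vectors
#'   `all_undetected`, `majority_undetected`, `analyzable` and the
#'   per-assay detection fractions.
#' @export
partition_by_detection <- function(ct, assays, majority_fraction = 0.5) {
  if (nrow(ct) == 0 || ncol(ct) == 0)
    ct_input_error("empty Ct matrix")
  if (!is.numeric(majority_fraction) || majority_fraction <= 0 ||
      majority_fraction > 1)
    ct_input_error("majority_fraction must be in (0, 1]")
  assays <- validate_assay_table(assays, ct)
  ids <- assays$assay_id[assays$role %in% c("target", "reference-candidate")]
  det <- colMeans(!is.na(unclass(ct)[, ids, drop = FALSE]))
  out <- list(
    all_undetected      = ids[det == 0],
    majority_undetected = ids[det > 0 & det < majority_fraction],
    analyzable          = ids[det >= majority_fraction],
    detection_fraction  = det)
  class(out) <- "detection_partition"
  out
}

#' @export
print.detection_partition <- function(x, ...) {
  cat(sprintf("<detection_partition> analyzable %d | majority-undetected %d | all-undetected %d\n",
              length(x$analyzable), length(x$majority_undetected),
              length(x$all_undetected)))
  invisible(x)
}

#' Delta-Ct normalization against endogenous reference assays
#'
#' `dCt(sample, assay) = Ct_assay(sample) - mean(Ct_ref(sample))`, the mean
#' taken arithmetically in Ct (log2) space over the reference assays, which
#' corresponds to the geometric mean of their linear quantities. The value
#' is missing wherever the target or any reference assay is undetected in
#' that sample. Lower dCt means higher relative expression.
#'
#' @param ct a [ct_matrix()].
#' @param reference_assays non-empty character vector of reference assay
#'   ids present in `ct`.
#' @return numeric matrix (samples x non-reference assays) of dCt values
#'   with `NA` for undefined cells.
#' @export
delta_ct <- function(ct, reference_assays) {
  if (length(reference_assays) == 0)
    ct_config_error("at least one reference assay is required")
  missing_ref <- setdiff(reference_assays, colnames(ct))
  if (length(missing_ref))
    ct_config_error(paste0("reference assay(s) absent from Ct matrix: ",
                           paste(missing_ref, collapse = ", ")))
  m <- unclass(ct)
  ref <- m[, reference_assays, drop = FALSE]
  norm <- rowMeans(ref)                       # NA if any reference undetected
  targets <- setdiff(colnames(m), reference_assays)
  sweep(m[, targets, drop = FALSE], 1, norm, `-`)
}

#' Relative expression by the comparative-Ct method
#'
#' `ddCt = dCt - mean(dCt of the calibrator group)` per assay, reported as
#' fold change `2^-ddCt`. The default calibrator is the age-matched control
#' group of each sample (control children for children, control adults for
#' adults), so case fold changes read directly as CD versus control.
#'
#' @param expr dCt matrix from [delta_ct()].
#' @param samples sample sheet.
#' @param calibrator either `"matched-age-controls"` (default) or a logical
#'   / character vector selecting a fixed calibrator sample set.
#' @return list with `fold_change` (samples x assays matrix of `2^-ddCt`)
#'   and `unavailable`, a data frame naming assay/calibrator combinations
#'   whose calibrator group had no detected value (cells left `NA`).
#' @export
relative_expression <- function(expr, samples, calibrator = "matched-age-controls") {
  samples <- validate_sample_table(samples)
  samples <- samples[match(rownames(expr), samples$sample_id), ]
  if (any(is.na(samples$sample_id)))
    ct_input_error("expression matrix contains samples absent from sample sheet")

  cal_sets <- if (identical(calibrator, "matched-age-controls")) {
    present <- intersect(c("child", "adult"), unique(samples$age_group))
    lapply(setNames(nm = present), function(g)
      samples$sample_id[samples$status == "control" & samples$age_group == g])
  } else {
    ids <- if (is.logical(calibrator)) rownames(expr)[calibrator] else calibrator
    list(all = intersect(ids, rownames(expr)))
  }
  if (any(lengths(cal_sets) == 0))
    ct_input_error("calibrator group selects no samples")

  fc <- expr * NA_real_
  unavailable <- data.frame(assay_id = character(), calibrator = character(),
                            stringsAsFactors = FALSE)
  for (gname in names(cal_sets)) {
    rows <- if (identical(calibrator, "matched-age-controls"))
      samples$sample_id[samples$age_group == gname] else rownames(expr)
    cal_mean <- colMeans(expr[cal_sets[[gname]], , drop = FALSE], na.rm = TRUE)
    empty <- !is.finite(cal_mean)
    if (any(empty))
      unavailable <- rbind(unavailable, data.frame(
        assay_id = colnames(expr)[empty], calibrator = gname,
        stringsAsFactors = FALSE))
    cal_mean[empty] <- NA_real_
    fc[rows, ] <- 2^(-sweep(expr[rows, , drop = FALSE], 2, cal_mean, `-`))
  }
  list(fold_change = fc, unavailable = unavailable)
}
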