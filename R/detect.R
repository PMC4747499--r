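## Inference on detection frequencies for low-abundance genes, plus the
## per-gene age-correlation screen.

#' Detection contingency table for a gene within an age stratum
#'
#' Builds the 2x2 table of detected/undetected wells by disease status
#' (rows CD, control; columns detected, undetected).
#'
#' @param ct a [ct_matrix()].
#' @param samples sample sheet.
#' @param assay assay id (column of `ct`).
#' @param stratum `"child"`, `"adult"` or `"all"`.
#' @return integer matrix of class `contingency_table`.
#' @export
detection_counts <- function(ct, samples, assay, stratum = "all") {
  samples <- validate_sample_table(samples, ct)
  if (!assay %in% colnames(ct))
    ct_input_error(paste0("assay not in Ct matrix: ", assay))
  keep <- if (stratum == "all") rep(TRUE, nrow(samples))
          else samples$age_group == stratum
  sub <- samples[keep, ]
  if (!any(sub$status == "CD") || !any(sub$status == "control"))
    ct_input_error(paste0("stratum '", stratum,
                          "' lacks CD or control samples"))
  det <- !is.na(unclass(ct)[sub$sample_id, assay])
  tab <- rbind(CD      = c(sum(det[sub$status == "CD"]),
                           sum(!det[sub$status == "CD"])),
               control = c(sum(det[sub$status == "control"]),
                           sum(!det[sub$status == "control"])))
  colnames(tab) <- c("detected", "undetected")
  structure(tab, class = c("contingency_table", class(tab)))
}

#' One-sided Fisher exact test on a detection table
#'
#' Exact hypergeometric tail probability of detection counts at least as
#' extreme as observed in the direction of greater detection in the first
#' row (CD). With table `[[a, b], [c, d]]` and fixed margins, the p-value
#' is `P(X >= a)` for `X` hypergeometric with `a + c` detected wells among
#' `a + b + c + d`, drawing the CD group of size `a + b`. Values are
#' returned at full precision; display convention is 2 decimals.
#'
#' @param table 2x2 non-negative integer matrix, rows = (CD, control),
#'   columns = (detected, undetected).
#' @param two_sided if `TRUE`, sum the probabilities of all tables with
#'   the same margins no more probable than the observed one.
#' @return the exact p-value.
#' @export
fisher_one_sided <- function(table, two_sided = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)))
    ct_input_error("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    ct_domain_error("cells must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m_det <- a + c; m_und <- b + d; k <- a + b
  support <- max(0, k - m_und):min(k, m_det)
  probs <- dhyper(support, m_det, m_und, k)
  if (two_sided) {
    sum(probs[probs <= dhyper(a, m_det, m_und, k) * (1 + 1e-7)])
  } else {
    sum(probs[support >= a])
  }
}

#' Spearman correlation of expression with age, per gene
#'
#' Screens every assay for monotone association between dCt and age in
#' years. Genes with fewer than `min_n` non-missing values are flagged
#' `insufficient`; genes with constant dCt (or constant age among the
#' usable samples) are flagged `undefined` with no numeric rho.
#'
#' @param expr dCt matrix from [delta_ct()].
#' @param samples sample sheet.
#' @param min_n minimum usable samples (default 4).
#' @return data frame: `assay_id`, `n`, `rho`, `p_value`, `flag`
#'   (`ok` / `insufficient` / `undefined`).
#' @export
age_correlation <- function(expr, samples, min_n = 4) {
  samples <- validate_sample_table(samples)
  age <- samples$age_years[match(rownames(expr), samples$sample_id)]
  rows <- lapply(colnames(expr), function(j) {
    x <- expr[, j]
    ok <- !is.na(x) & !is.na(age)
    n <- sum(ok)
    if (n < min_n)
      return(data.frame(assay_id = j, n = n, rho = NA_real_,
                        p_value = NA_real_, flag = "insufficient",
                        stringsAsFactors = FALSE))
    if (sd(x[ok]) == 0 || sd(age[ok]) == 0)
      return(data.frame(assay_id = j, n = n, rho = NA_real_,
                        p_value = NA_real_, flag = "undefined",
                        stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      cor.test(x[ok], age[ok], method = "spearman", exact = FALSE))
    data.frame(assay_id = j, n = n, rho = unname(ct$estimate),
               p_value = ct$p.value, flag = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
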