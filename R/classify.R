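## Age-of-onset gene classification.
##
## Three posterior tables feed the taxonomy: CD vs control in children,
## CD vs control in adults, and CD children vs CD adults ("difference"
## comparison). Two tiers of evidence are distinguished:
##   significant: Pr(mu != 0) > 0.5 (the Bayes-rule call under equal costs)
##   reported:    Pr(mu != 0) >= 0.5 (a posterior worth displaying; at
##                exactly 0.50 a gene is shown but not called)
## Absent values (NA) are neither. Categories, applied in order:
##   1. difference significant and both strata reported
##        -> higher_adults / higher_children by the larger stratum posterior
##   2. difference significant and exactly one stratum significant
##        -> only_that_stratum
##   3. difference not significant: both strata significant -> similar_both;
##      exactly one -> only_that_stratum; none -> not_altered
## The two-tier rule is what lets a gene sit at 0.50 in one stratum yet
## still be classed as more altered in the other.

CATEGORIES <- c("similar_both", "only_children", "only_adults",
                "higher_adults", "higher_children", "not_altered")

#' Classify genes by age-of-onset expression pattern
#'
#' @param posteriors data frame with columns `gene`, `p_child`, `p_adult`,
#'   `p_diff` — posterior probabilities of a non-zero effect
#'   (`Pr(mu != 0)`) for the children, adult and children-vs-adult CD
#'   comparisons; `NA` = unreported. Alternatively pass three
#'   `posterior_table`s via [posteriors_to_classification_input()].
#' @param directions optional data frame `gene`, `dir_child`, `dir_adult`
#'   with values `up_in_CD` / `down_in_CD`.
#' @param high_significance_cutoff posterior at or above which an altered
#'   gene is flagged high-significance (heuristic display split,
#'   default 0.60).
#' @return data frame of class `classification_report`: inputs plus
#'   `category`, `significance` (`high`/`low`, altered genes only) and
#'   any supplied direction columns.
#' @export
classify_genes <- function(posteriors, directions = NULL,
                           high_significance_cutoff = 0.60) {
  need <- c("gene", "p_child", "p_adult", "p_diff")
  miss <- setdiff(need, names(posteriors))
  if (length(miss))
    ct_input_error(paste0("posteriors missing column(s): ",
                          paste(miss, collapse = ", ")))
  if (anyDuplicated(posteriors$gene))
    ct_input_error("duplicate gene in posteriors")
  bad <- unlist(posteriors[need[-1]])
  if (any(!is.na(bad) & (bad < 0 | bad > 1)))
    ct_domain_error("posterior probabilities must lie in [0, 1]")

  one <- function(pc, pa, pd) {
    rep_c <- !is.na(pc) && pc >= 0.5; sig_c <- !is.na(pc) && pc > 0.5
    rep_a <- !is.na(pa) && pa >= 0.5; sig_a <- !is.na(pa) && pa > 0.5
    sig_d <- !is.na(pd) && pd > 0.5
    if (sig_d && rep_c && rep_a) {
      if (pa == pc)
        message("classify_genes: equal stratum posteriors with a significant difference; labelling higher_adults")
      if (pa >= pc) "higher_adults" else "higher_children"
    } else if (sig_d && xor(sig_c, sig_a)) {
      if (sig_c) "only_children" else "only_adults"
    } else if (sig_c && sig_a) {
      "similar_both"
    } else if (sig_c) {
      "only_children"
    } else if (sig_a) {
      "only_adults"
    } else "not_altered"
  }
  out <- posteriors[, need]
  out$category <- if (nrow(out)) mapply(one, out$p_child, out$p_adult,
                                        out$p_diff) else character(0)
  altered <- out$category != "not_altered"
  hi <- pmax(ifelse(is.na(out$p_child), -Inf, out$p_child),
             ifelse(is.na(out$p_adult), -Inf, out$p_adult))
  out$significance <- ifelse(!altered, NA_character_,
                             ifelse(hi >= high_significance_cutoff,
                                    "high", "low"))
  if (!is.null(directions)) {
    idx <- match(out$gene, directions$gene)
    out$dir_child <- directions$dir_child[idx]
    out$dir_adult <- directions$dir_adult[idx]
  }
  class(out) <- c("classification_report", class(out))
  out
}

#' Category counts of a classification report
#'
#' @param report a `classification_report`.
#' @return named integer vector over all categories plus `n_altered`,
#'   the total number of differentially regulated genes.
#' @export
classification_counts <- function(report) {
  counts <- vapply(CATEGORIES, function(cat)
    sum(report$category == cat), integer(1))
  c(counts, n_altered = sum(report$category != "not_altered"))
}

#' Assemble classification input from three posterior tables
#'
#' @param post_child,post_adult,post_diff `posterior_table`s for the
#'   CD-vs-control children, CD-vs-control adults and CD-children-vs-
#'   CD-adults comparisons (same assay set).
#' @param assays optional assay sheet used to translate assay ids to gene
#'   symbols.
#' @return list with `posteriors` and `directions` data frames ready for
#'   [classify_genes()]. Ineligible genes carry `NA` posteriors.
#' @export
posteriors_to_classification_input <- function(post_child, post_adult,
                                               post_diff, assays = NULL) {
  ids <- post_child$assay_id
  if (!setequal(ids, post_adult$assay_id) || !setequal(ids, post_diff$assay_id))
    ct_input_error("the three posterior tables must cover the same gene set")
  gene <- if (!is.null(assays)) assays$gene[match(ids, assays$assay_id)] else ids
  grab <- function(tab) {
    i <- match(ids, tab$assay_id)
    list(p = tab$p_alt[i], dir = ifelse(tab$direction[i] == "up_in_A",
                                        "up_in_CD",
                                        ifelse(tab$direction[i] == "down_in_A",
                                               "down_in_CD", NA_character_)))
  }
  ch <- grab(post_child); ad <- grab(post_adult); df <- grab(post_diff)
  list(posteriors = data.frame(gene = gene, p_child = ch$p, p_adult = ad$p,
                               p_diff = df$p, stringsAsFactors = FALSE),
       directions = data.frame(gene = gene, dir_child = ch$dir,
                               dir_adult = ad$dir, stringsAsFactors = FALSE))
}

#' Published age-of-onset posterior table bundled with the package
#'
#' A transcription of the 20-gene posterior-probability table from the
#' duodenal qPCR study of child- versus adult-onset celiac disease that
#' motivates this package: `Pr(mu != 0)` for CD vs control in children
#' and adults and for CD children vs CD adults, with unreported entries
#' (posterior below 0.5) as `NA`. Useful as a worked classification
#' example and as a check that the taxonomy rules reproduce the published
#' gene categories.
#'
#' @return data frame with columns `gene`, `p_child`, `p_adult`, `p_diff`.
#' @export
published_onset_posteriors <- function() {
  path <- system.file("extdata", "cd_onset_posteriors.csv",
                      package = "ctbayes", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
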