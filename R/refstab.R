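## Reference-gene stability ranking.
##
## Two complementary algorithms, both operating on raw Ct values (already
## log2-scale, so no further transform):
##
##  * geNorm: for candidates j,k the per-sample log-ratio is
##    a_jk(s) = Ct_j(s) - Ct_k(s); V_jk = sd_s(a_jk); the stability
##    M_j = mean_{k != j} V_jk. The least stable (highest M) gene is
##    removed and M recomputed, down to the final indistinguishable pair.
##    The pairwise-variation series V_{k/k+1} compares mean-Ct
##    normalization factors built from the best k and k+1 genes.
##
##  * a model-based (NormFinder-style) score: after per-sample centering
##    (subtracting each sample's mean Ct over candidates, which removes
##    sample-specific loading), a gene's score is the mean over sample
##    groups of |group bias| + within-group sd / sqrt(group size). No
##    numeric parity with the original NormFinder software is claimed;
##    the score captures the same inter- + intra-group decomposition.
##
## Samples with any undetected candidate are excluded listwise (both
## algorithms assume complete matrices); the count is reported via message.

candidate_submatrix <- function(ct, candidates, min_candidates) {
  missing_ids <- setdiff(candidates, colnames(ct))
  if (length(missing_ids))
    ct_input_error(paste0("candidate assay(s) absent from Ct matrix: ",
                          paste(missing_ids, collapse = ", ")))
  if (length(candidates) < min_candidates)
    ct_input_error(sprintf("need >= %d candidate assays, got %d",
                           min_candidates, length(candidates)))
  det <- colSums(!is.na(unclass(ct)[, candidates, drop = FALSE]))
  if (any(det < 2))
    ct_input_error(paste0("candidate(s) detected in < 2 samples: ",
                          paste(candidates[det < 2], collapse = ", ")))
  m <- unclass(ct)[, candidates, drop = FALSE]
  keep <- complete.cases(m)
  if (sum(!keep) > 0)
    message(sprintf("stability ranking: dropped %d sample(s) with undetected candidates",
                    sum(!keep)))
  if (sum(keep) < 2)
    ct_input_error("fewer than 2 complete samples across candidates")
  m[keep, , drop = FALSE]
}

## mean pairwise-ratio sd of each column against the others
genorm_m <- function(m) {
  g <- ncol(m)
  vapply(seq_len(g), function(j) {
    mean(vapply(setdiff(seq_len(g), j),
                function(k) sd(m[, j] - m[, k]), numeric(1)))
  }, numeric(1))
}

#' Rank candidate reference genes by geNorm stability
#'
#' @param ct a [ct_matrix()].
#' @param candidates character vector of >= 3 candidate assay ids.
#' @return object of class `stability_ranking`: a list with `method`,
#'   `scores` (data frame `assay_id`, `score` = full-set M, `rank`; final
#'   pair shares rank 1), `exclusion_order` (least stable first) and
#'   `v_series` (pairwise variations `V_{k/k+1}` for k = 2..n-1).
#' @export
genorm_rank <- function(ct, candidates) {
  m <- candidate_submatrix(ct, candidates, min_candidates = 3)
  full_m <- setNames(genorm_m(m), colnames(m))

  excluded <- character(0)
  work <- m
  while (ncol(work) > 2) {
    mv <- genorm_m(work)
    worst <- colnames(work)[order(-mv, colnames(work))[1]]
    excluded <- c(excluded, worst)
    work <- work[, setdiff(colnames(work), worst), drop = FALSE]
  }
  stability_order <- c(sort(colnames(work)), rev(excluded))  # most stable first

  ranks <- seq_along(stability_order)
  ranks[2] <- 1L                                       # final pair tied
  scores <- data.frame(assay_id = stability_order,
                       score = unname(full_m[stability_order]),
                       rank = ranks, stringsAsFactors = FALSE)

  v_series <- NULL
  n <- length(stability_order)
  if (n >= 3) {
    nf <- vapply(2:n, function(k)
      rowMeans(m[, stability_order[1:k], drop = FALSE]), numeric(nrow(m)))
    v <- vapply(seq_len(n - 2), function(i) sd(nf[, i] - nf[, i + 1]),
                numeric(1))
    v_series <- setNames(v, sprintf("V%d/%d", 2:(n - 1), 3:n))
  }
  structure(list(method = "genorm", scores = scores,
                 exclusion_order = excluded, v_series = v_series,
                 n_samples_used = nrow(m)),
            class = "stability_ranking")
}

#' Rank candidate reference genes by a model-based stability score
#'
#' @inheritParams genorm_rank
#' @param groups factor or character vector of group labels, either named
#'   by sample id or aligned with the rows of `ct`. Needs >= 2 groups with
#'   >= 2 samples each.
#' @return object of class `stability_ranking` (no exclusion order or V
#'   series for this method); scores are in cycles, lower = more stable.
#' @export
normfinder_rank <- function(ct, candidates, groups) {
  if (!is.null(names(groups))) groups <- groups[rownames(ct)]
  if (length(groups) != nrow(ct))
    ct_input_error("groups must label every sample of the Ct matrix")
  m <- candidate_submatrix(ct, candidates, min_candidates = 2)
  g <- factor(groups[match(rownames(m), rownames(ct))])
  tab <- table(g)
  if (length(tab) < 2) ct_input_error("need >= 2 sample groups")
  if (any(tab < 2)) ct_input_error("every group needs >= 2 usable samples")

  centered <- m - rowMeans(m)
  score <- vapply(colnames(m), function(j) {
    x <- centered[, j]
    grand <- mean(x)
    per_group <- vapply(levels(g), function(lv) {
      xs <- x[g == lv]
      abs(mean(xs) - grand) + sd(xs) / sqrt(length(xs))
    }, numeric(1))
    mean(per_group)
  }, numeric(1))

  ord <- order(score, names(score))
  scores <- data.frame(assay_id = names(score)[ord],
                       score = unname(score[ord]),
                       rank = seq_along(score), stringsAsFactors = FALSE)
  structure(list(method = "normfinder", scores = scores,
                 exclusion_order = NULL, v_series = NULL,
                 n_samples_used = nrow(m)),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat(sprintf("<stability_ranking> method=%s, %d candidates, %d samples used\n",
              x$method, nrow(x$scores), x$n_samples_used))
  print(utils::head(x$scores, 5))
  invisible(x)
}

#' Select endogenous reference assays from one or more rankings
#'
#' Takes the `k` assays with the best (lowest) mean rank across the
#' supplied rankings; ties are broken lexicographically by assay id and
#' reported via message.
#'
#' @param rankings a single `stability_ranking` or a list of them.
#' @param k number of reference assays to select.
#' @return character vector of `k` assay ids.
#' @export
select_references <- function(rankings, k = 2) {
  if (inherits(rankings, "stability_ranking")) rankings <- list(rankings)
  if (length(rankings) == 0) ct_input_error("at least one ranking required")
  if (k < 1) ct_input_error("k must be >= 1")
  ids <- Reduce(intersect, lapply(rankings, function(r) r$scores$assay_id))
  if (k > length(ids))
    ct_input_error(sprintf("k = %d exceeds the %d shared candidates",
                           k, length(ids)))
  mean_rank <- rowMeans(vapply(rankings, function(r)
    r$scores$rank[match(ids, r$scores$assay_id)], numeric(length(ids))))
  ord <- order(mean_rank, ids)
  cut <- sort(mean_rank)[k]
  if (sum(mean_rank == cut) > 1 && sum(mean_rank < cut) + sum(mean_rank == cut) > k)
    message(sprintf("select_references: tie at mean rank %.2f broken lexicographically",
                    cut))
  ids[ord][seq_len(k)]
}
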