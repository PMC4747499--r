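## Spike-and-slab two-groups model for difference-of-means statistics.
##
## For each gene i the statistic is t_i, the difference of group means of
## dCt, with Welch standard error s_i and standardized z_i = t_i / s_i.
## The model places prior mass pi0 on mu_i = 0 (null: z_i ~ N(0,1)) and
## 1 - pi0 on a Gaussian slab for the standardized effect
## (z_i ~ N(0, 1 + tau2)). The posterior null probability
##   Pr(mu_i = 0 | z_1..z_m)
## depends on all statistics through the shared hyperparameters (pi0,
## tau2), fitted either by marginal maximum likelihood (empirical Bayes)
## or by a Gibbs sampler over latent null indicators. Rejection follows
## the Bayes rule for 0-1 costs: reject when Pr(mu_i != 0) exceeds
## c_fn / (c_fp + c_fn), i.e. 0.5 under equal costs (strict, so a gene at
## exactly 0.5 is not called).

select_samples <- function(samples, selector) {
  ids <- if (is.function(selector)) {
    samples$sample_id[selector(samples)]
  } else if (is.logical(selector)) {
    samples$sample_id[selector]
  } else if (is.list(selector)) {
    keep <- rep(TRUE, nrow(samples))
    for (nm in names(selector)) keep <- keep & samples[[nm]] %in% selector[[nm]]
    samples$sample_id[keep]
  } else as.character(selector)
  if (length(ids) == 0) ct_input_error("group selector matches no samples")
  ids
}

#' Per-gene difference-of-means statistics between two sample groups
#'
#' Group means use detected samples only. Genes with fewer than
#' `min_per_group` detected samples in either group are flagged
#' ineligible (`eligible = FALSE`), never silently dropped.
#'
#' @param expr dCt matrix from [delta_ct()] (samples x assays).
#' @param samples sample sheet.
#' @param group_a,group_b group selectors: a character vector of sample
#'   ids, a logical vector over the sheet, a predicate function, or a
#'   named list of column filters such as
#'   `list(status = "CD", age_group = "child")`.
#' @param min_per_group minimum detected samples per group (default 3).
#' @param comparison optional label carried through downstream tables.
#' @return data frame of class `statistic_table`: `assay_id`, `n_a`,
#'   `n_b`, `t` (mean A - mean B, cycles; negative = higher expression in
#'   A), `s` (Welch SE), `z`, `eligible`.
#' @export
group_statistics <- function(expr, samples, group_a, group_b,
                             min_per_group = 3, comparison = NA_character_) {
  samples <- validate_sample_table(samples)
  if (min_per_group < 2) ct_input_error("min_per_group must be >= 2")
  ids_a <- intersect(select_samples(samples, group_a), rownames(expr))
  ids_b <- intersect(select_samples(samples, group_b), rownames(expr))
  if (length(ids_a) == 0 || length(ids_b) == 0)
    ct_input_error("group selector matches no samples in the expression matrix")
  if (length(intersect(ids_a, ids_b)))
    ct_input_error("the two groups overlap")

  one <- function(j) {
    a <- expr[ids_a, j]; a <- a[!is.na(a)]
    b <- expr[ids_b, j]; b <- b[!is.na(b)]
    na <- length(a); nb <- length(b)
    ok <- na >= min_per_group && nb >= min_per_group
    t <- if (na && nb) mean(a) - mean(b) else NA_real_
    s <- if (ok) sqrt(var(a) / na + var(b) / nb) else NA_real_
    if (!is.na(s) && s == 0) { ok <- FALSE; s <- NA_real_ }
    df <- if (ok) {
      va <- var(a) / na; vb <- var(b) / nb
      (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    } else NA_real_
    c(n_a = na, n_b = nb, t = t, s = s,
      z = if (ok) t / s else NA_real_, df = df, eligible = ok)
  }
  res <- t(vapply(colnames(expr), one, numeric(7)))
  out <- data.frame(assay_id = rownames(res), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$eligible <- as.logical(out$eligible)
  attr(out, "comparison") <- comparison
  class(out) <- c("statistic_table", class(out))
  out
}

mixture_loglik <- function(z, pi0, tau2) {
  sum(log(pi0 * dnorm(z) + (1 - pi0) * dnorm(z, 0, sqrt(1 + tau2))))
}

## Map a t-scale ratio to the normal scale through its Welch df:
## z_cal = qnorm(pt(t/s, df)), evaluated in the tails via log
## probabilities. With 5-13 samples per group the raw ratio has heavy
## t-tails that a N(0,1) spike misreads as signal; the calibrated value
## is standard normal under the null. Falls back to the raw ratio where
## df is unavailable.
calibrate_t <- function(z, df) {
  out <- z
  use <- is.finite(z) & !is.na(df) & is.finite(df)
  lo <- stats::pt(-abs(z[use]), df[use], log.p = TRUE)
  out[use] <- -sign(z[use]) * qnorm(lo, log.p = TRUE)
  out
}

## z values fed to the mixture model from a statistic_table or bare vector
model_z <- function(stats, calibrate = TRUE) {
  if (is.numeric(stats)) return(stats[is.finite(stats)])
  z <- stats$z[stats$eligible]
  df <- if (calibrate && !is.null(stats$df)) stats$df[stats$eligible]
        else rep(NA_real_, length(z))
  calibrate_t(z, df)[is.finite(z)]
}

#' Empirical-Bayes fit of the spike-and-slab hyperparameters
#'
#' Maximizes the marginal likelihood
#' `prod_i [pi0 N(z_i; 0, 1) + (1 - pi0) N(z_i; 0, 1 + tau2)]` over
#' `pi0 in [0.01, 1]`, `tau2 in [0, tau2_max]` by bounded quasi-Newton
#' from several starting points.
#'
#' @param stats a `statistic_table` from [group_statistics()], or a bare
#'   numeric vector of z values.
#' @param tau2_max upper bound for the slab variance (default 100).
#' @param calibrate map each t-ratio to the normal scale through its
#'   Welch degrees of freedom before fitting (default `TRUE`; ignored for
#'   bare z vectors or tables without a `df` column).
#' @param null_guard the mixture is unidentifiable near `tau2 = 0`: a
#'   slight variance excess can be explained either as "all null" or as
#'   "nothing null with a negligible slab", with opposite posteriors.
#'   With the guard (default `TRUE`) the fit falls back to `pi0 = 1`
#'   unless the mixture beats the all-null model by more than the
#'   boundary likelihood-ratio allowance `qchisq(0.95, 2) / 2`.
#' @return list of class `ct_hyper`: `pi0`, `tau2`, `loglik`, `method`,
#'   `convergence`, `null_preferred`.
#' @export
fit_two_groups_eb <- function(stats, tau2_max = 100, calibrate = TRUE,
                              null_guard = TRUE) {
  z <- model_z(stats, calibrate)
  if (length(z) < 5)
    ct_input_error("need >= 5 eligible genes to fit hyperparameters")

  obj <- function(par) -mixture_loglik(z, par[1], par[2])
  starts <- rbind(c(0.9, 4), c(0.5, 9), c(0.99, 1), c(0.7, 25), c(0.3, 2))
  fits <- apply(starts, 1, function(s)
    tryCatch(optim(s, obj, method = "L-BFGS-B",
                   lower = c(0.01, 0), upper = c(1, tau2_max)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    ct_stop("hyperparameter optimizer failed from every start",
            "ctbayes_optim_error")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (all(vapply(fits, `[[`, numeric(1), "convergence") != 0)) {
    cond <- structure(
      class = c("ctbayes_optim_error", "ctbayes_error", "error", "condition"),
      list(message = "hyperparameter optimizer did not converge",
           call = sys.call(), best = best, diagnostics = fits))
    stop(cond)
  }
  pars <- best$par
  loglik <- -best$value
  null_preferred <- FALSE
  if (null_guard) {
    ll_null <- mixture_loglik(z, 1, 0)
    if (loglik - ll_null < qchisq(0.95, 2) / 2) {
      pars <- c(1, 0)
      loglik <- ll_null
      null_preferred <- TRUE
    }
  }
  structure(list(pi0 = pars[1], tau2 = pars[2],
                 loglik = loglik, method = "eb",
                 convergence = best$convergence,
                 null_preferred = null_preferred, n_genes = length(z)),
            class = "ct_hyper")
}

#' Gibbs-sampler fit of the spike-and-slab model
#'
#' Samples latent null indicators (Bernoulli full conditional with the
#' slab collapsed), slab effects (conjugate normal), `pi0` (Beta update)
#' and `tau2` (inverse-gamma update given the sampled slab effects).
#'
#' @inheritParams fit_two_groups_eb
#' @param prior_spec list: `a_pi`, `b_pi` (Beta prior on pi0, default
#'   uniform), `a_tau`, `b_tau` (inverse-gamma prior on tau2, default
#'   shape 2 rate 2), optional `fix_pi0` to clamp pi0.
#' @param n_iter,burn_in total and discarded sweeps.
#' @param seed integer seed; identical seed and data give identical chains.
#' @param calibrate as in [fit_two_groups_eb()].
#' @return list of class `ct_hyper` with posterior means `pi0`, `tau2`,
#'   per-gene posterior null frequencies `p_null_mcmc`, and the retained
#'   `chains` (matrix with columns pi0, tau2).
#' @export
fit_two_groups_gibbs <- function(stats, prior_spec = list(), n_iter = 2000,
                                 burn_in = 500, seed = 1L, calibrate = TRUE) {
  if (!(n_iter > burn_in && burn_in >= 0))
    ct_input_error("need n_iter > burn_in >= 0")
  z <- model_z(stats, calibrate)
  if (length(z) < 5)
    ct_input_error("need >= 5 eligible genes to fit hyperparameters")
  a_pi  <- prior_spec$a_pi  %||% 1
  b_pi  <- prior_spec$b_pi  %||% 1
  a_tau <- prior_spec$a_tau %||% 2
  b_tau <- prior_spec$b_tau %||% 2
  fix_pi0 <- prior_spec$fix_pi0

  set.seed(seed)
  m <- length(z)
  pi0 <- fix_pi0 %||% 0.9
  tau2 <- 4
  keep <- n_iter - burn_in
  chains <- matrix(NA_real_, keep, 2, dimnames = list(NULL, c("pi0", "tau2")))
  null_count <- numeric(m)

  for (it in seq_len(n_iter)) {
    d0 <- pi0 * dnorm(z)
    d1 <- (1 - pi0) * dnorm(z, 0, sqrt(1 + tau2))
    p_nonnull <- ifelse(d0 + d1 == 0, 0, d1 / (d0 + d1))
    gamma <- rbinom(m, 1, p_nonnull)
    m1 <- sum(gamma)
    ## slab effects for the non-null genes: delta | z, tau2
    delta2_sum <- if (m1 > 0) {
      v <- tau2 / (1 + tau2)
      sum(rnorm(m1, z[gamma == 1] * v, sqrt(v))^2)
    } else 0
    if (is.null(fix_pi0)) pi0 <- rbeta(1, a_pi + (m - m1), b_pi + m1)
    tau2 <- 1 / rgamma(1, a_tau + m1 / 2, rate = b_tau + delta2_sum / 2)
    if (it > burn_in) {
      chains[it - burn_in, ] <- c(pi0, tau2)
      null_count <- null_count + (gamma == 0)
    }
  }
  structure(list(pi0 = mean(chains[, "pi0"]), tau2 = mean(chains[, "tau2"]),
                 p_null_mcmc = null_count / keep, chains = chains,
                 method = "gibbs", convergence = 0L, n_genes = m),
            class = "ct_hyper")
}

#' @export
print.ct_hyper <- function(x, ...) {
  cat(sprintf("<ct_hyper %s> pi0 = %.3f, tau2 = %.3f (%d genes)\n",
              x$method, x$pi0, x$tau2, x$n_genes))
  invisible(x)
}

#' Posterior null probabilities under fitted hyperparameters
#'
#' `p_i = pi0 N(z_i; 0, 1) / [pi0 N(z_i; 0, 1) + (1 - pi0) N(z_i; 0, 1 + tau2)]`.
#' Dependence of each gene on all statistics enters through the shared
#' fitted hyperparameters.
#'
#' @param stats a `statistic_table` (or numeric z vector).
#' @param hyper a `ct_hyper` fit, or `list(pi0 =, tau2 =)`.
#' @param calibrate as in [fit_two_groups_eb()]; must match the setting
#'   used when fitting `hyper`.
#' @return data frame of class `posterior_table`: per gene `z`, `p_null`,
#'   `p_alt` (= 1 - p_null exactly), `direction` (`up_in_A` when t < 0,
#'   i.e. higher expression in group A), plus the input statistics.
#'   Ineligible genes keep `NA` posteriors.
#' @export
posterior_null <- function(stats, hyper, calibrate = TRUE) {
  pi0 <- hyper$pi0; tau2 <- hyper$tau2
  if (is.null(pi0) || is.null(tau2) || pi0 <= 0 || pi0 > 1)
    ct_domain_error("hyper must supply pi0 in (0,1] and tau2 >= 0")
  if (tau2 < 0) ct_domain_error("tau2 must be >= 0")
  if (is.numeric(stats))
    stats <- data.frame(assay_id = names(stats) %||%
                          paste0("g", seq_along(stats)),
                        t = NA_real_, s = NA_real_, z = stats,
                        eligible = is.finite(stats),
                        stringsAsFactors = FALSE)
  z <- calibrate_t(stats$z, if (calibrate && !is.null(stats$df)) stats$df
                             else rep(NA_real_, nrow(stats)))
  d0 <- pi0 * dnorm(z)
  d1 <- (1 - pi0) * dnorm(z, 0, sqrt(1 + tau2))
  p <- d0 / (d0 + d1)
  p[d0 + d1 == 0] <- pi0      # both tails underflow: prior odds
  p[!stats$eligible] <- NA_real_
  out <- stats
  out$p_null <- p
  out$p_alt <- 1 - p
  out$direction <- ifelse(is.na(out$t) | out$t == 0, "none",
                          ifelse(out$t < 0, "up_in_A", "down_in_A"))
  attr(out, "hyper") <- list(pi0 = pi0, tau2 = tau2,
                             method = hyper$method %||% "fixed")
  attr(out, "comparison") <- attr(stats, "comparison")
  class(out) <- unique(c("posterior_table", class(out)))
  out
}

#' Bayes-rule decision on posterior probabilities
#'
#' Rejects the null for gene i iff `Pr(mu_i != 0) > c_fn / (c_fp + c_fn)`
#' (strict). Equal costs give the 0.5 threshold, so a posterior of exactly
#' 0.50 is not rejected. The Bayesian FDR estimate is the mean posterior
#' null probability over the rejected set.
#'
#' @param post a `posterior_table`.
#' @param c_fp,c_fn positive misclassification costs (default equal).
#' @return `post` with a `reject` column, of class `decision_table`;
#'   attributes `threshold`, `costs` and `bayes_fdr`.
#' @export
decide <- function(post, c_fp = 1, c_fn = 1) {
  if (!is.numeric(c_fp) || !is.numeric(c_fn) || c_fp <= 0 || c_fn <= 0)
    ct_input_error("costs must be positive")
  threshold <- c_fn / (c_fp + c_fn)
  out <- post
  out$reject <- !is.na(out$p_alt) & out$p_alt > threshold
  boundary <- which(!is.na(out$p_alt) & abs(out$p_alt - threshold) < 1e-12)
  if (length(boundary))
    message(sprintf("decide: %d gene(s) exactly at the %.3f boundary (not rejected): %s",
                    length(boundary), threshold,
                    paste(out$assay_id[boundary], collapse = ", ")))
  attr(out, "threshold") <- threshold
  attr(out, "costs") <- c(c_fp = c_fp, c_fn = c_fn)
  attr(out, "bayes_fdr") <- if (any(out$reject)) mean(out$p_null[out$reject])
                            else NA_real_
  class(out) <- unique(c("decision_table", class(out)))
  out
}
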