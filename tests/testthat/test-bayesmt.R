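toy_stats <- function() {
  ids <- c(paste0("A", 1:3), paste0("B", 1:3))
  expr <- matrix(c(4, 5, 6, 7, 8, 9), 6, 1, dimnames = list(ids, "G"))
  samples <- make_samples(ids, rep(c("CD", "control"), each = 3), "child")
  group_statistics(expr, samples, list(status = "CD"),
                   list(status = "control"))
}

test_that("group statistics implement the Welch difference of means", {
  st <- toy_stats()
  expect_equal(st$t, -3)                        # 5 - 8: A more expressed
  expect_equal(st$s, sqrt(1 / 3 + 1 / 3))       # ~0.8165
  expect_equal(st$z, -3 / sqrt(2 / 3), tolerance = 1e-6)  # ~-3.674
  expect_equal(st$df, 4)                        # equal variances, 3 v 3
  expect_true(st$eligible)

  # identical groups -> t = 0, z = 0
  ids <- sprintf("S%d", 1:6)
  expr0 <- matrix(rep(c(4, 5, 6), 2), 6, 1, dimnames = list(ids, "G"))
  samples0 <- make_samples(ids, rep(c("CD", "control"), each = 3), "adult")
  st0 <- group_statistics(expr0, samples0, list(status = "CD"),
                          list(status = "control"))
  expect_equal(st0$t, 0)
  expect_equal(st0$z, 0)
})

test_that("small groups are flagged ineligible, not dropped", {
  ids <- sprintf("S%d", 1:6)
  expr <- matrix(c(4, 5, NA, 7, 8, 9, 4, 5, 6, 7, 8, 9), 6, 2,
                 dimnames = list(ids, c("G1", "G2")))
  samples <- make_samples(ids, rep(c("CD", "control"), each = 3), "child")
  st <- group_statistics(expr, samples, list(status = "CD"),
                         list(status = "control"), min_per_group = 3)
  expect_equal(nrow(st), 2)
  expect_false(st$eligible[st$assay_id == "G1"])
  expect_true(st$eligible[st$assay_id == "G2"])
  expect_true(is.na(st$z[st$assay_id == "G1"]))

  expect_error(group_statistics(expr, samples, list(status = "CD"),
                                list(status = "none")),
               class = "ctbayes_input_error")
})

test_that("posterior null probabilities follow the closed form", {
  z <- c(-3, -1, 0, 0.5, 2, 4)
  # pi0 = 1 -> p = 1 everywhere
  expect_equal(posterior_null(z, list(pi0 = 1, tau2 = 5))$p_null,
               rep(1, 6))
  # tau2 = 0 -> densities identical -> p = pi0
  expect_equal(posterior_null(z, list(pi0 = 0.7, tau2 = 0))$p_null,
               rep(0.7, 6))
  # z = 0, pi0 = 0.5, tau2 = 3 -> phi(0;0,1)/(phi(0;0,1)+phi(0;0,4)) = 2/3
  expect_equal(posterior_null(0, list(pi0 = 0.5, tau2 = 3))$p_null,
               2 / 3, tolerance = 1e-12)
  expect_error(posterior_null(z, list(pi0 = 0.5, tau2 = -1)),
               class = "ctbayes_domain_error")
  # p_null + p_alt = 1 exactly
  pt <- posterior_null(z, list(pi0 = 0.4, tau2 = 8))
  expect_identical(pt$p_null + pt$p_alt, rep(1, 6))
})

test_that("posterior null decreases monotonically in |z|", {
  z <- seq(0, 8, by = 0.25)
  p <- posterior_null(z, list(pi0 = 0.8, tau2 = 4))$p_null
  expect_true(all(diff(p) < 0))
  p_neg <- posterior_null(-z, list(pi0 = 0.8, tau2 = 4))$p_null
  expect_equal(p, p_neg)
})

test_that("closed-form posteriors agree with numeric integration", {
  set.seed(101)
  for (i in 1:100) {
    z <- runif(1, -6, 6); pi0 <- runif(1, 0.02, 0.99)
    tau2 <- runif(1, 0.05, 40)
    expect_equal(posterior_null(z, list(pi0 = pi0, tau2 = tau2))$p_null,
                 oracle_posterior_null(z, pi0, tau2), tolerance = 1e-8)
  }
})

test_that("EB fit matches a grid-search oracle on a small z set", {
  z <- c(-4.1, -2.2, -0.3, 0.1, 0.4, -0.6, 1.2, 2.8, 0.05, -0.9, 3.5, -0.2)
  fit <- fit_two_groups_eb(z)
  grid <- expand.grid(pi0 = seq(0.01, 1, length.out = 200),
                      tau2 = seq(0, 25, length.out = 200))
  ll <- mapply(function(p, t)
    sum(log(p * dnorm(z) + (1 - p) * dnorm(z, 0, sqrt(1 + t)))),
    grid$pi0, grid$tau2)
  best <- grid[which.max(ll), ]
  expect_lte(abs(fit$pi0 - best$pi0), (1 - 0.01) / 199)
  expect_lte(abs(fit$tau2 - best$tau2), 25 / 199)
  expect_gte(fit$loglik, max(ll) - 1e-6)
})

test_that("EB fit handles the all-null boundary", {
  expect_equal(fit_two_groups_eb(rep(0, 50))$pi0, 1)
  expect_error(fit_two_groups_eb(c(0, 1)), class = "ctbayes_input_error")
})

test_that("t-ratio calibration restores a standard normal null", {
  st <- toy_stats()
  zc <- ctbayes:::model_z(st, calibrate = TRUE)
  expect_equal(zc, qnorm(pt(st$z, st$df)), tolerance = 1e-10)
  # calibration shrinks heavy t tails toward the normal
  expect_lt(abs(zc), abs(st$z))
  # without df information the raw ratio passes through
  expect_equal(ctbayes:::model_z(st$z, calibrate = TRUE), st$z)
})

test_that("the Gibbs sampler is seeded, honors a clamped pi0, and recovers truth", {
  set.seed(55)
  sim <- simulate_z(400, pi0 = 0.8, tau2 = 9)
  g1 <- fit_two_groups_gibbs(sim$z, n_iter = 600, burn_in = 200, seed = 4)
  g2 <- fit_two_groups_gibbs(sim$z, n_iter = 600, burn_in = 200, seed = 4)
  expect_identical(g1$chains, g2$chains)

  clamped <- fit_two_groups_gibbs(sim$z, prior_spec = list(fix_pi0 = 1),
                                  n_iter = 200, burn_in = 50, seed = 4)
  expect_equal(clamped$p_null_mcmc, rep(1, 400))
  expect_equal(clamped$pi0, 1)

  expect_error(fit_two_groups_gibbs(sim$z, n_iter = 100, burn_in = 100),
               class = "ctbayes_input_error")
})

test_that("EB and Gibbs hyperparameter estimates agree", {
  set.seed(77)
  sim <- simulate_z(2000, pi0 = 0.8, tau2 = 9)
  eb <- fit_two_groups_eb(sim$z)
  gb <- fit_two_groups_gibbs(sim$z, n_iter = 1500, burn_in = 500, seed = 77)
  expect_lt(abs(eb$pi0 - gb$pi0), 0.05)
  expect_lt(abs(gb$pi0 - 0.8), 0.05)
})

test_that("the Bayes rule rejects strictly above the cost threshold", {
  pt <- posterior_null(c(0, 1, 2), list(pi0 = 0.5, tau2 = 4))
  pt$p_alt <- c(0.50, 0.73, 0.90)
  pt$p_null <- 1 - pt$p_alt
  d <- decide(pt)
  expect_equal(attr(d, "threshold"), 0.5)
  expect_equal(d$reject, c(FALSE, TRUE, TRUE))   # 0.50 is NOT rejected
  expect_equal(attr(d, "bayes_fdr"), mean(c(0.27, 0.10)))

  d2 <- decide(pt, c_fp = 3, c_fn = 1)
  expect_equal(attr(d2, "threshold"), 0.25)
  expect_error(decide(pt, c_fp = 0), class = "ctbayes_input_error")
})

test_that("the 0.5-posterior rule is at least as powerful as BH at q=0.05", {
  set.seed(31)
  sim <- simulate_z(2000, pi0 = 0.8, tau2 = 9)
  fit <- fit_two_groups_eb(sim$z)
  post <- decide(posterior_null(sim$z, fit))
  bayes_hits <- sum(post$reject & sim$nonnull)
  pvals <- 2 * pnorm(-abs(sim$z))
  bh_hits <- sum(p.adjust(pvals, "BH") <= 0.05 & sim$nonnull)
  expect_gte(bayes_hits, bh_hits)
})
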