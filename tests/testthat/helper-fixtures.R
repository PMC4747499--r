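# Shared fixture builders. Everything is constructed in code; no files.

make_ct <- function(values, sample_ids = NULL, assay_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sample_ids %||% sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- assay_ids %||% sprintf("A%02d", seq_len(ncol(m)))
  ct_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_samples <- function(ids, status, age_group,
                         age_years = seq(5, by = 2, length.out = length(ids))) {
  data.frame(sample_id = ids, age_years = age_years,
             age_group = age_group, status = status,
             stringsAsFactors = FALSE)
}

make_assays <- function(ids, role = "target", gene = ids,
                        category = "none") {
  data.frame(assay_id = ids, gene = gene, role = role,
             category = category, stringsAsFactors = FALSE)
}

# --- independent oracles ---------------------------------------------------

# geNorm M by explicit double loop over pairwise ratio sds
oracle_genorm_m <- function(m) {
  g <- ncol(m)
  out <- numeric(g)
  for (j in seq_len(g)) {
    vs <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      ratios <- m[, j] - m[, k]
      mu <- sum(ratios) / length(ratios)
      vs <- c(vs, sqrt(sum((ratios - mu)^2) / (length(ratios) - 1)))
    }
    out[j] <- mean(vs)
  }
  setNames(out, colnames(m))
}

# model-based stability score by direct formula evaluation
oracle_normfinder <- function(m, groups) {
  centered <- m - rowMeans(m)
  g <- factor(groups)
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- centered[, j]
    grand <- mean(x)
    acc <- c()
    for (lv in levels(g)) {
      xs <- x[g == lv]
      acc <- c(acc, abs(mean(xs) - grand) + sd(xs) / sqrt(length(xs)))
    }
    out[j] <- mean(acc)
  }
  setNames(out, colnames(m))
}

# one-sided Fisher p by exhaustive hypergeometric enumeration with choose()
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d; mdet <- a + c; k <- a + b
  total <- 0
  for (x in 0:min(k, mdet)) {
    y <- k - x
    if (y > n - mdet) next
    if (x >= a)
      total <- total + choose(mdet, x) * choose(n - mdet, y)
  }
  total / choose(n, k)
}

# posterior null probability via numeric integration of the slab marginal
oracle_posterior_null <- function(z, pi0, tau2) {
  slab <- integrate(function(mu) dnorm(z - mu) * dnorm(mu, 0, sqrt(tau2)),
                    -Inf, Inf, rel.tol = 1e-12)$value
  pi0 * dnorm(z) / (pi0 * dnorm(z) + (1 - pi0) * slab)
}

# draw z values from the spike-and-slab two-groups model
simulate_z <- function(m, pi0, tau2) {
  nonnull <- runif(m) > pi0
  z <- rnorm(m)
  z[nonnull] <- rnorm(sum(nonnull), 0, sqrt(1 + tau2))
  list(z = z, nonnull = nonnull)
}

# small panel of candidate assays for stability simulations: a designated
# stable pair plus noisy disease-affected genes
stability_panel <- function() {
  data.frame(
    assay_id = sprintf("REF%02d", 1:8),
    gene = sprintf("G%02d", 1:8),
    role = "reference-candidate", category = "none",
    baseline_ct = c(24, 26, 22, 23, 25, 27, 28, 21),
    sd_ct = c(0.1, 0.1, 1.0, 1.2, 1.5, 1.0, 1.3, 1.1),
    effect_child = c(0, 0, -1.5, 1.0, -0.8, 0.6, -1.2, 0.9),
    effect_adult = c(0, 0, -0.5, 1.5, -1.2, 0.3, -0.6, 1.4),
    stringsAsFactors = FALSE)
}
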