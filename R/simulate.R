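## Synthetic Ct data generator.
##
## Emulates a stratified duodenal qPCR case-control design: four strata
## (CD children, control children, CD adults, control adults), a 48-assay
## TaqMan-style panel, Gaussian latent Ct per assay per group, and
## deterministic limit-of-detection censoring (latent Ct above `lod_ct`
## is reported undetected). Disease effects are additive shifts of the
## latent Ct in CD relative to controls, per age stratum; negative shifts
## mean up-regulation in CD (lower Ct = more template).

#' Default 48-assay panel
#'
#' The default panel reproduces the bookkeeping of the motivating study
#' design: 3 commercial housekeeping assays (deliberately noisy, so that
#' stability ranking rejects them), 2 designated stable reference
#' candidates (PUS10, GLB1), 38 analyzable disease-panel targets, 2 assays
#' silent in duodenum (all wells censored) and 3 low-abundance Th17
#' cytokines detected in a minority of samples, one of which (IL21) is
#' detected preferentially in cases. Effects are Ct shifts in CD versus
#' control per age stratum (cycles; negative = up in CD).
#'
#' @return data frame with columns `assay_id`, `gene`, `role`, `category`,
#'   `baseline_ct`, `sd_ct`, `effect_child`, `effect_adult`.
#' @export
default_assay_panel <- function() {
  row <- function(gene, role, category, base, sd, ec, ea)
    data.frame(gene = gene, role = role, category = category,
               baseline_ct = base, sd_ct = sd,
               effect_child = ec, effect_adult = ea,
               stringsAsFactors = FALSE)
  p <- rbind(
    ## commercial housekeeping genes: no disease effect but high variance
    row("RPLP0", "housekeeping", "none", 19, 1.4, 0, 0),
    row("HPRT1", "housekeeping", "none", 26, 1.5, 0, 0),
    row("18S",   "housekeeping", "none", 12, 1.6, 0, 0),
    ## stable endogenous reference candidates
    row("PUS10", "reference-candidate", "CD-locus", 24, 0.10, 0, 0),
    row("GLB1",  "reference-candidate", "none",     26, 0.10, 0, 0),
    ## altered similarly in children and adults
    row("C2orf74", "target", "CD-locus", 25, 0.8, -1.5, -1.5),
    row("CCR6",    "target", "Th17",     24, 0.8, -1.5, -1.5),
    row("FASLG",   "target", "CD-locus", 27, 0.8, -1.5, -1.5),
    row("JAK2",    "target", "Th17",     23, 0.8, -1.5, -1.5),
    row("IL23A",   "target", "Th17",     28, 1.0, -0.8, -0.8),
    row("TAGAP",   "target", "CD-locus", 25, 1.0, -0.8, -0.8),
    row("UBE2L3",  "target", "CD-locus", 22, 1.0, -0.8, -0.8),
    ## altered only in children
    row("TNFSF18", "target", "CD-locus", 28, 0.8, -1.5,  0.0),
    row("ICOSLG",  "target", "CD-locus", 25, 0.9,  0.8,  0.0),
    ## altered only in adults
    row("IL1RL1",  "target", "CD-locus", 27, 0.8,  0.0, -1.5),
    row("CD28",    "target", "CD-locus", 26, 1.0,  0.0, -0.8),
    row("STAT3",   "target", "Th17",     22, 1.0,  0.0, -0.8),
    row("TMEM187", "target", "CD-locus", 27, 1.0,  0.0, -0.8),
    row("VAMP3",   "target", "both",     23, 1.0,  0.0, -0.8),
    row("ZFP36L1", "target", "CD-locus", 21, 1.0,  0.0, -0.8),
    ## altered in both, larger effect in adults
    row("CCR4",    "target", "Th17",     26, 0.8, -1.0, -2.0),
    row("IL6",     "target", "Th17",     29, 0.9, -0.8, -2.0),
    row("IL18RAP", "target", "CD-locus", 25, 0.9, -0.6, -1.2),
    row("PLEK",    "target", "CD-locus", 24, 0.9, -0.6, -1.2),
    ## down-regulated in CD, larger effect in children
    row("C1orf106", "target", "CD-locus", 25, 0.8, 1.2, 0.6),
    ## panel members without a true effect
    row("IL18R1", "target", "CD-locus", 26, 1.0, 0, 0),
    row("SH2B3",  "target", "CD-locus", 24, 1.0, 0, 0),
    row("ETS1",   "target", "CD-locus", 23, 0.9, 0, 0),
    row("RGS1",   "target", "CD-locus", 24, 1.1, 0, 0),
    row("LPP",    "target", "CD-locus", 23, 0.9, 0, 0),
    row("SCHIP1", "target", "CD-locus", 26, 1.1, 0, 0),
    row("CCR3",   "target", "CD-locus", 27, 0.9, 0, 0),
    row("IRAK1",  "target", "CD-locus", 25, 1.1, 0, 0),
    row("POU2AF1","target", "CD-locus", 26, 0.9, 0, 0),
    row("THEMIS", "target", "CD-locus", 25, 1.1, 0, 0),
    row("PTPRK",  "target", "CD-locus", 24, 0.9, 0, 0),
    row("RUNX3",  "target", "CD-locus", 23, 1.1, 0, 0),
    row("CIITA",  "target", "CD-locus", 26, 0.9, 0, 0),
    row("SOCS1",  "target", "both",     24, 1.1, 0, 0),
    row("PRKCQ",  "target", "CD-locus", 25, 0.9, 0, 0),
    row("ZMIZ1",  "target", "CD-locus", 23, 1.1, 0, 0),
    row("TLR7",   "target", "none",     27, 0.9, 0, 0),
    row("ARHGAP31","target","CD-locus", 26, 1.1, 0, 0),
    ## silent in duodenum: latent Ct far above any detection limit
    row("ADAD1", "target", "CD-locus", 45, 1.0, 0, 0),
    row("OLIG3", "target", "CD-locus", 45, 1.0, 0, 0),
    ## low-abundance Th17 cytokines near the detection limit
    row("IL17F", "target", "Th17", 36.2, 1.2,  0.0,  0.0),
    row("IL21",  "target", "Th17", 37.2, 1.6, -2.4, -2.4),
    row("IL22",  "target", "Th17", 36.2, 1.2,  0.0,  0.0))
  ## deterministic TaqMan-style assay ids; IL1RL1 keeps its catalogue id
  ## (the probe for the soluble-protein isoform)
  p$assay_id <- sprintf("Hs%08d_m1", 1000001L + 7L * seq_len(nrow(p)))
  p$assay_id[p$gene == "IL1RL1"] <- "Hs01073297_m1"
  p[, c("assay_id", "gene", "role", "category",
        "baseline_ct", "sd_ct", "effect_child", "effect_adult")]
}

#' Simulation configuration
#'
#' Defaults mirror the motivating study design: 13 CD children, 7 control
#' children, 6 CD adults, 5 control adults; stratum ages (mean +/- sd years)
#' 5.6 +/- 0.6, 8.1 +/- 2.2, 38.3 +/- 3.4 and 50.6 +/- 10.9; a 48-assay
#' panel; detection limit 35 cycles.
#'
#' @param n_cd_children,n_ctrl_children,n_cd_adults,n_ctrl_adults stratum
#'   sizes (each >= 2).
#' @param age_means_sd named list of `c(mean, sd)` ages in years for
#'   `cd_child`, `ctrl_child`, `cd_adult`, `ctrl_adult`.
#' @param panel assay panel data frame, see [default_assay_panel()].
#' @param lod_ct detection limit in cycles; latent Ct above it is censored.
#' @param seed integer seed governing all randomness of the generator.
#' @return a validated config of class `sim_config`.
#' @export
sim_config <- function(n_cd_children = 13, n_ctrl_children = 7,
                       n_cd_adults = 6, n_ctrl_adults = 5,
                       age_means_sd = list(cd_child  = c(5.6, 0.6),
                                           ctrl_child = c(8.1, 2.2),
                                           cd_adult  = c(38.3, 3.4),
                                           ctrl_adult = c(50.6, 10.9)),
                       panel = default_assay_panel(),
                       lod_ct = 35, seed = 1L) {
  cfg <- list(n_cd_children = n_cd_children, n_ctrl_children = n_ctrl_children,
              n_cd_adults = n_cd_adults, n_ctrl_adults = n_ctrl_adults,
              age_means_sd = age_means_sd, panel = panel,
              lod_ct = lod_ct, seed = as.integer(seed))
  sizes <- unlist(cfg[1:4])
  if (any(sizes < 2))
    ct_config_error("all stratum sizes must be >= 2")
  if (!is.numeric(lod_ct) || lod_ct <= 0)
    ct_config_error("lod_ct must be a positive cycle count")
  need <- c("assay_id", "gene", "role", "baseline_ct", "sd_ct",
            "effect_child", "effect_adult")
  if (!all(need %in% names(panel)))
    ct_config_error(paste0("panel missing column(s): ",
                           paste(setdiff(need, names(panel)), collapse = ", ")))
  if (anyDuplicated(panel$assay_id))
    ct_config_error("panel assay ids must be unique")
  if (!all(panel$role %in% ASSAY_ROLES))
    ct_config_error("every assay needs exactly one role from the closed set")
  if (any(panel$sd_ct < 0))
    ct_config_error("per-assay sds must be >= 0")
  nm <- c("cd_child", "ctrl_child", "cd_adult", "ctrl_adult")
  if (!all(nm %in% names(age_means_sd)) ||
      any(vapply(age_means_sd[nm], function(x) x[2] < 0, logical(1))))
    ct_config_error("age_means_sd needs non-negative sds for all four strata")
  class(cfg) <- "sim_config"
  cfg
}

## positive ages by rejection sampling from the stratum Gaussian
rtnorm_pos <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Generate a synthetic Ct dataset
#'
#' Latent Ct for sample s, assay a is
#' `baseline_ct[a] + effect[a, stratum(s)] * [status == CD] + N(0, sd_ct[a])`;
#' wells with latent Ct above `lod_ct` are emitted undetected. The same
#' config and seed always reproduce the dataset bit-identically.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `ct_simulation` with elements `ct`
#'   ([ct_matrix()]), `samples`, `assays`, `truth` (ground-truth mean
#'   differences per comparison) and `config`.
#' @export
simulate_ct_dataset <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(seed %||% config$seed)
  p <- config$panel
  strata <- data.frame(
    stratum = c("cd_child", "ctrl_child", "cd_adult", "ctrl_adult"),
    n = c(config$n_cd_children, config$n_ctrl_children,
          config$n_cd_adults, config$n_ctrl_adults),
    status = c("CD", "control", "CD", "control"),
    age_group = c("child", "child", "adult", "adult"),
    prefix = c("CDc", "CTc", "CDa", "CTa"),
    stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    ms <- config$age_means_sd[[s$stratum]]
    data.frame(sample_id = sprintf("%s%02d", s$prefix, seq_len(s$n)),
               age_years = round(rtnorm_pos(s$n, ms[1], ms[2]), 1),
               age_group = s$age_group, status = s$status,
               stringsAsFactors = FALSE)
  }))
  eff <- function(age_group) if (age_group == "child")
    p$effect_child else p$effect_adult
  m <- matrix(NA_real_, nrow(samples), nrow(p),
              dimnames = list(samples$sample_id, p$assay_id))
  for (i in seq_len(nrow(samples))) {
    shift <- if (samples$status[i] == "CD") eff(samples$age_group[i]) else 0
    m[i, ] <- p$baseline_ct + shift + rnorm(nrow(p), 0, p$sd_ct)
  }
  m[m > config$lod_ct] <- NA_real_
  m[!is.na(m)] <- round(m[!is.na(m)], 4)

  truth <- do.call(rbind, lapply(
    list(c("cd_vs_ctrl_children", "effect_child", NA),
         c("cd_vs_ctrl_adults", "effect_adult", NA),
         c("cd_children_vs_cd_adults", "effect_child", "effect_adult")),
    function(cmp) {
      d <- if (is.na(cmp[3])) p[[cmp[2]]] else p[[cmp[2]]] - p[[cmp[3]]]
      data.frame(assay_id = p$assay_id, gene = p$gene, comparison = cmp[1],
                 true_diff = d, null = d == 0,
                 direction = ifelse(d == 0, "none",
                                    ifelse(d < 0, "up", "down")),
                 stringsAsFactors = FALSE)
    }))
  rownames(truth) <- NULL

  structure(list(ct = ct_matrix(m), samples = samples,
                 assays = p[, c("assay_id", "gene", "role", "category")],
                 truth = truth, config = config),
            class = "ct_simulation")
}

#' Write a simulated dataset as the standard CSV trio
#'
#' Emits `ct.csv` (wide Ct matrix with `Undetermined` sentinels),
#' `samples.csv`, `assays.csv` and `truth.csv` under `dir`.
#'
#' @param sim result of [simulate_ct_dataset()].
#' @param dir output directory (created if absent).
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ct_table(sim$ct, file.path(dir, "ct.csv"))
  write.csv(sim$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(sim$assays, file.path(dir, "assays.csv"), row.names = FALSE)
  write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
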