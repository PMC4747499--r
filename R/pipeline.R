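## End-to-end orchestration: simulate or load a dataset, filter by
## detection, select references, quantify, run the four Bayesian
## comparisons, detection tests, the age screen, and classification;
## optionally write the full TSV/JSON artifact bundle.

COMPARISONS <- list(
  cd_vs_ctrl_children = list(a = list(status = "CD", age_group = "child"),
                             b = list(status = "control", age_group = "child")),
  cd_vs_ctrl_adults   = list(a = list(status = "CD", age_group = "adult"),
                             b = list(status = "control", age_group = "adult")),
  cd_children_vs_cd_adults = list(a = list(status = "CD", age_group = "child"),
                                  b = list(status = "CD", age_group = "adult")),
  ctrl_children_vs_ctrl_adults = list(
    a = list(status = "control", age_group = "child"),
    b = list(status = "control", age_group = "adult")))

#' Default pipeline configuration
#'
#' @param simulate `NULL`, or a list of [sim_config()] arguments — when
#'   present the dataset is simulated rather than read.
#' @param io list of paths `ct`, `samples`, `assays` (ignored when
#'   simulating) and optional `out` directory.
#' @param filters list: `majority_fraction` (default 0.5), `min_per_group`
#'   (default 3), `sentinel`.
#' @param model list: `engine` (`"eb"` or `"gibbs"`), `tau2_max`,
#'   `n_iter`, `burn_in`.
#' @param costs list `c_fp`, `c_fn` (default equal).
#' @param refs list: `k` (default 2), `candidates` (`"analyzable"` to rank
#'   every analyzable assay, or explicit ids), `methods`.
#' @param seed integer seed.
#' @return config list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(), io = list(), filters = list(),
                            model = list(), costs = list(), refs = list(),
                            seed = 1L) {
  cfg <- list(
    simulate = simulate, io = io,
    filters = list(majority_fraction = filters$majority_fraction %||% 0.5,
                   min_per_group = filters$min_per_group %||% 3,
                   sentinel = filters$sentinel %||% "Undetermined"),
    model = list(engine = model$engine %||% "eb",
                 tau2_max = model$tau2_max %||% 100,
                 n_iter = model$n_iter %||% 2000,
                 burn_in = model$burn_in %||% 500),
    costs = list(c_fp = costs$c_fp %||% 1, c_fn = costs$c_fn %||% 1),
    refs = list(k = refs$k %||% 2,
                candidates = refs$candidates %||% "analyzable",
                methods = refs$methods %||% c("genorm", "normfinder")),
    seed = as.integer(seed))
  if (!cfg$model$engine %in% c("eb", "gibbs"))
    ct_config_error("model engine must be 'eb' or 'gibbs'")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a JSON file
#'
#' Recognised sections mirror [pipeline_config()]: `simulate`, `io`,
#' `filters`, `model`, `costs`, `refs`, `seed`.
#'
#' @param path JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) ct_input_error(paste0("config not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[intersect(names(raw), names(formals(pipeline_config)))])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    ct_stop(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), "ctbayes_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Stages: data acquisition (simulation or the CSV trio), detection
#' partition, reference-gene selection (geNorm + model-based score on the
#' analyzable assays, disease-by-age groups), dCt quantification against
#' the selected references, the four Bayesian comparisons (children,
#' adults, CD by age, controls by age), detection-frequency Fisher tests
#' for majority-undetected genes, the Spearman age screen, relative
#' expression export and gene classification. If `config$io$out` is set,
#' [write_pipeline_outputs()] persists the bundle.
#'
#' @param config a `pipeline_config`, a list of its arguments, or a path
#'   to a JSON config file.
#' @return list of class `pipeline_result` with all intermediate and
#'   final tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  log_lines <- c(sprintf("ctbayes %s | seed %d | engine %s",
                         as.character(packageVersion("ctbayes")),
                         config$seed, config$model$engine))

  dat <- stage("data", {
    if (length(config$simulate) || !length(config$io$ct)) {
      sim <- simulate_ct_dataset(do.call(sim_config, config$simulate),
                                 seed = config$seed)
      log_lines <- c(log_lines, "data: simulated dataset")
      sim
    } else {
      io <- config$io
      for (f in c("ct", "samples", "assays"))
        if (is.null(io[[f]]))
          ct_input_error(paste0("config$io missing required path: ", f))
      ct <- read_ct_table(io$ct, sentinel = config$filters$sentinel)
      list(ct = ct, samples = read_sample_table(io$samples, ct),
           assays = read_assay_table(io$assays, ct), truth = NULL)
    }
  })
  ct <- dat$ct; samples <- dat$samples; assays <- dat$assays

  part <- stage("detection-partition",
                partition_by_detection(ct, assays, config$filters$majority_fraction))
  log_lines <- c(log_lines, sprintf(
    "filter: %d analyzable, %d majority-undetected, %d all-undetected",
    length(part$analyzable), length(part$majority_undetected),
    length(part$all_undetected)))

  refsel <- stage("reference-selection", {
    cand <- if (identical(config$refs$candidates, "analyzable"))
      part$analyzable else config$refs$candidates
    groups <- setNames(paste(samples$status, samples$age_group, sep = "_"),
                       samples$sample_id)
    rankings <- list()
    if ("genorm" %in% config$refs$methods)
      rankings$genorm <- suppressMessages(genorm_rank(ct, cand))
    if ("normfinder" %in% config$refs$methods)
      rankings$normfinder <- suppressMessages(normfinder_rank(ct, cand, groups))
    list(rankings = rankings,
         references = select_references(rankings, config$refs$k))
  })
  log_lines <- c(log_lines, paste0("references: ",
                                   paste(refsel$references, collapse = ", ")))

  expr <- stage("delta-ct", {
    e <- delta_ct(ct, refsel$references)
    e[, intersect(colnames(e), setdiff(part$analyzable, refsel$references)),
      drop = FALSE]
  })
  log_lines <- c(log_lines, sprintf("delta-ct: %d genes x %d samples",
                                    ncol(expr), nrow(expr)))

  posteriors <- stage("bayesian-tests", {
    lapply(setNames(nm = names(COMPARISONS)), function(nm) {
      cmp <- COMPARISONS[[nm]]
      st <- group_statistics(expr, samples, cmp$a, cmp$b,
                             min_per_group = config$filters$min_per_group,
                             comparison = nm)
      hyper <- if (config$model$engine == "gibbs")
        fit_two_groups_gibbs(st, n_iter = config$model$n_iter,
                             burn_in = config$model$burn_in,
                             seed = config$seed)
      else fit_two_groups_eb(st, tau2_max = config$model$tau2_max)
      decide(posterior_null(st, hyper),
             c_fp = config$costs$c_fp, c_fn = config$costs$c_fn)
    })
  })

  detect_tests <- stage("detection-tests", {
    rows <- list()
    for (a in part$majority_undetected) for (str in c("child", "adult")) {
      tab <- detection_counts(ct, samples, a, str)
      rows[[paste(a, str)]] <- data.frame(
        assay_id = a, gene = assays$gene[match(a, assays$assay_id)],
        stratum = str, cd_detected = tab[1, 1], cd_undetected = tab[1, 2],
        ctrl_detected = tab[2, 1], ctrl_undetected = tab[2, 2],
        p_one_sided = fisher_one_sided(tab), stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(assay_id = character(), gene = character(),
                    stratum = character(), cd_detected = integer(),
                    cd_undetected = integer(), ctrl_detected = integer(),
                    ctrl_undetected = integer(), p_one_sided = numeric(),
                    stringsAsFactors = FALSE)
  })

  age_screen <- stage("age-correlation", age_correlation(expr, samples))
  rel_expr <- stage("relative-expression",
                    relative_expression(expr, samples))

  classification <- stage("classification", {
    inp <- posteriors_to_classification_input(
      posteriors$cd_vs_ctrl_children, posteriors$cd_vs_ctrl_adults,
      posteriors$cd_children_vs_cd_adults, assays)
    classify_genes(inp$posteriors, inp$directions)
  })
  log_lines <- c(log_lines, paste0(
    "classification: ",
    paste(sprintf("%s=%d", names(classification_counts(classification)),
                  classification_counts(classification)), collapse = " ")))

  result <- structure(
    list(ct = ct, samples = samples, assays = assays, truth = dat$truth,
         partition = part, reference_selection = refsel, expr = expr,
         posteriors = posteriors, detection_tests = detect_tests,
         age_screen = age_screen, relative_expression = rel_expr,
         classification = classification, config = config, log = log_lines),
    class = "pipeline_result")
  if (length(config$io$out))
    write_pipeline_outputs(result, config$io$out)
  result
}

write_tsv <- function(df, path, digits = 4) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), NA, formatC(x, digits = digits, format = "f")))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", na = "")
  invisible(path)
}

posterior_tsv <- function(tab) {
  data.frame(assay_id = tab$assay_id, comparison = attr(tab, "comparison"),
             n_a = as.integer(tab$n_a), n_b = as.integer(tab$n_b),
             t = tab$t, se = tab$s, z = tab$z, p_null = tab$p_null,
             p_alt = tab$p_alt, reject = tab$reject,
             direction = tab$direction, stringsAsFactors = FALSE)
}

#' Write the pipeline artifact bundle
#'
#' Emits tab-delimited UTF-8 tables (posteriors at 4 decimals): dCt and
#' fold-change matrices, stability report, one posterior/decision table
#' per comparison, detection tests, age screen, classification report, a
#' JSON summary with category counts and fitted hyperparameters, and a
#' run log.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @export
write_pipeline_outputs <- function(result, dir) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) ct_stop(paste0("cannot create ", dir), "ctbayes_io_error")

  expr_df <- data.frame(sample_id = rownames(result$expr),
                        round(result$expr, 4), check.names = FALSE)
  write_tsv(expr_df, file.path(dir, "delta_ct.tsv"))
  fc <- result$relative_expression$fold_change
  write_tsv(data.frame(sample_id = rownames(fc), round(fc, 4),
                       check.names = FALSE),
            file.path(dir, "fold_change.tsv"))

  stab <- do.call(rbind, lapply(result$reference_selection$rankings,
                                function(r) cbind(method = r$method, r$scores)))
  write_tsv(stab, file.path(dir, "stability.tsv"))

  for (nm in names(result$posteriors))
    write_tsv(posterior_tsv(result$posteriors[[nm]]),
              file.path(dir, paste0("posteriors_", nm, ".tsv")))

  write_tsv(result$detection_tests, file.path(dir, "detection_tests.tsv"))
  write_tsv(result$age_screen, file.path(dir, "age_correlation.tsv"))
  write_tsv(as.data.frame(result$classification),
            file.path(dir, "classification.tsv"))

  counts <- classification_counts(result$classification)
  summary <- list(
    seed = result$config$seed,
    references = result$reference_selection$references,
    n_analyzable = length(result$partition$analyzable),
    category_counts = as.list(counts[CATEGORIES]),
    n_altered = unname(counts["n_altered"]),
    hyperparameters = lapply(result$posteriors, function(p) attr(p, "hyper")),
    bayes_fdr = lapply(result$posteriors, function(p)
      attr(p, "bayes_fdr")))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  invisible(x)
}
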