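test_that("taxonomy rules reproduce the published single-gene examples", {
  one <- function(pc, pa, pd) {
    classify_genes(data.frame(gene = "g", p_child = pc, p_adult = pa,
                              p_diff = pd))$category
  }
  expect_equal(one(0.65, 0.65, NA), "similar_both")     # JAK2
  expect_equal(one(0.73, NA, 0.54), "only_children")    # TNFSF18
  expect_equal(one(NA, 0.55, NA), "only_adults")        # CD28
  expect_equal(one(0.58, 0.79, 0.72), "higher_adults")  # CCR4
  expect_equal(one(0.57, 0.51, 0.52), "higher_children")# C1orf106
  # reported-but-not-significant 0.50 still supports a higher_adults call
  expect_equal(one(0.50, 0.63, 0.91), "higher_adults")  # IL6
  expect_equal(one(NA, NA, NA), "not_altered")
  expect_equal(one(0.2, 0.3, 0.9), "not_altered")       # diff alone is not enough
})

test_that("the bundled published table classifies exactly as printed", {
  rep <- classify_genes(published_onset_posteriors())
  counts <- classification_counts(rep)
  expect_equal(unname(counts["similar_both"]), 7L)
  expect_equal(unname(counts["only_adults"]), 6L)
  expect_equal(unname(counts["only_children"]), 2L)
  expect_equal(unname(counts["higher_adults"]), 4L)
  expect_equal(unname(counts["higher_children"]), 1L)
  expect_equal(unname(counts["n_altered"]), 20L)

  by_cat <- split(rep$gene, rep$category)
  expect_setequal(by_cat$similar_both,
                  c("C2orf74", "CCR6", "FASLG", "JAK2", "IL23A", "TAGAP",
                    "UBE2L3"))
  expect_setequal(by_cat$only_adults,
                  c("IL1RL1", "CD28", "STAT3", "TMEM187", "VAMP3", "ZFP36L1"))
  expect_setequal(by_cat$only_children, c("TNFSF18", "ICOSLG"))
  expect_setequal(by_cat$higher_adults, c("CCR4", "IL6", "IL18RAP", "PLEK"))
  expect_equal(by_cat$higher_children, "C1orf106")
})

test_that("category counts partition the gene set", {
  set.seed(67)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    ps <- function() ifelse(runif(n) < 0.3, NA, round(runif(n, 0.3, 1), 2))
    rep <- classify_genes(data.frame(gene = paste0("g", 1:n),
                                     p_child = ps(), p_adult = ps(),
                                     p_diff = ps()))
    counts <- classification_counts(rep)
    expect_equal(sum(counts[ctbayes:::CATEGORIES]), n)
  }
})

test_that("swapping the strata swaps the mirrored categories", {
  set.seed(71)
  n <- 60
  ps <- function() ifelse(runif(n) < 0.3, NA, round(runif(n, 0.3, 1), 2))
  base <- data.frame(gene = paste0("g", 1:n), p_child = ps(),
                     p_adult = ps(), p_diff = ps())
  swapped <- transform(base, p_child = p_adult, p_adult = p_child)
  c1 <- classify_genes(base)$category
  c2 <- classify_genes(swapped)$category
  map <- c(similar_both = "similar_both", not_altered = "not_altered",
           only_children = "only_adults", only_adults = "only_children",
           higher_children = "higher_adults", higher_adults = "higher_children")
  # ties between equal stratum posteriors break toward adults, so exclude
  tied <- !is.na(base$p_child) & !is.na(base$p_adult) &
    base$p_child == base$p_adult
  expect_equal(c2[!tied], unname(map[c1[!tied]]))
})

test_that("classification inputs are validated", {
  expect_error(classify_genes(data.frame(gene = "g", p_child = 0.4)),
               class = "ctbayes_input_error")
  expect_error(classify_genes(data.frame(gene = c("g", "g"), p_child = 0.4,
                                         p_adult = 0.6, p_diff = NA)),
               class = "ctbayes_input_error")
  expect_error(classify_genes(data.frame(gene = "g", p_child = 1.4,
                                         p_adult = 0.6, p_diff = NA)),
               class = "ctbayes_domain_error")
  tabs <- lapply(1:3, function(i)
    data.frame(assay_id = c("a", "b"), p_alt = 0.6, t = -1,
               direction = "up_in_A"))
  tabs[[3]]$assay_id <- c("a", "zzz")
  expect_error(posteriors_to_classification_input(tabs[[1]], tabs[[2]],
                                                  tabs[[3]]),
               class = "ctbayes_input_error")
})

test_that("the pipeline is deterministic and writes a faithful bundle", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- function(out) pipeline_config(io = list(out = out), seed = 11)
  res1 <- suppressMessages(run_pipeline(cfg(dir1)))
  res2 <- suppressMessages(run_pipeline(cfg(dir2)))

  files <- list.files(dir1)
  expect_true(all(c("delta_ct.tsv", "stability.tsv", "classification.tsv",
                    "summary.json", "run_log.txt",
                    "posteriors_cd_vs_ctrl_children.tsv") %in% files))
  for (f in files)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     info = f)

  # posterior TSV round-trips at 4 decimals
  tab <- read.delim(file.path(dir1, "posteriors_cd_vs_ctrl_adults.tsv"))
  orig <- res1$posteriors$cd_vs_ctrl_adults
  expect_equal(tab$p_null, round(orig$p_null, 4), tolerance = 1e-9)

  # JSON summary counts match the in-memory classification
  js <- jsonlite::read_json(file.path(dir1, "summary.json"),
                            simplifyVector = TRUE)
  counts <- classification_counts(res1$classification)
  expect_equal(unlist(js$category_counts),
               counts[ctbayes:::CATEGORIES][names(js$category_counts)])
  expect_equal(js$n_altered, unname(counts["n_altered"]))
})

test_that("a null simulation yields an overwhelmingly unaltered panel", {
  panel <- default_assay_panel()
  panel$effect_child <- 0
  panel$effect_adult <- 0
  res <- suppressMessages(
    run_pipeline(pipeline_config(simulate = list(panel = panel), seed = 19)))
  counts <- classification_counts(res$classification)
  # truth is all-null; allow a handful of false positives
  expect_lte(unname(counts["n_altered"]), 6L)
})

test_that("pipeline errors name the failing interface", {
  err <- tryCatch(
    run_pipeline(pipeline_config(io = list(ct = "x.csv", assays = "y.csv"))),
    error = identity)
  expect_s3_class(err, "ctbayes_stage_error")
  expect_match(conditionMessage(err), "samples")
})

test_that("the classify CLI writes the category-count JSON", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "post.csv")
  write.csv(published_onset_posteriors(), csv, row.names = FALSE, na = "")
  out <- file.path(dir, "out")
  suppressMessages(ctbayes_cli(c("classify", "--posteriors", csv,
                                 "--out", out)))
  js <- jsonlite::read_json(file.path(out, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$similar_both, 7)
  expect_equal(js$only_adults, 6)
  expect_equal(js$only_children, 2)
  expect_equal(js$higher_adults, 4)
  expect_equal(js$higher_children, 1)
  expect_equal(js$n_altered, 20)

  expect_error(suppressMessages(ctbayes_cli(c("frobnicate"))),
               class = "ctbayes_input_error")
})

test_that("empty gene sets still produce valid headed tables", {
  rep <- classify_genes(data.frame(gene = character(), p_child = numeric(),
                                   p_adult = numeric(), p_diff = numeric()))
  expect_equal(nrow(rep), 0)
  counts <- classification_counts(rep)
  expect_true(all(counts == 0))
  dir <- withr::local_tempdir()
  ctbayes:::write_tsv(as.data.frame(rep), file.path(dir, "empty.tsv"))
  back <- read.delim(file.path(dir, "empty.tsv"))
  expect_equal(nrow(back), 0)
  expect_true("category" %in% names(back))
})
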