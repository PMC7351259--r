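test_that("the search front end wraps every method with association stats", {
  ch <- generate_cohort(snp_table(), n_per_group = 150, seed = 2)
  fit <- barcode_search(ch, order = 2, method = "htga", pop_size = 16,
                        iterations = 15, seed = 3)
  expect_s3_class(fit, "barcode_search")
  expect_s3_class(fit$association, "barcode_assoc")
  expect_identical(fit$association$difference, fit$best_fitness)
  expect_output(print(fit), "HTGA")
  expect_output(summary(fit), "OR")

  ex <- barcode_search(ch, order = 1, method = "exhaustive")
  expect_null(ex$history)
  expect_identical(ex$best_fitness, exhaustive_search(ch, 1)$best_fitness)
  expect_error(plot(ex), "no convergence history")

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("histories can be written and parsed back", {
  ch <- generate_cohort(snp_table(), n_per_group = 100, seed = 2)
  fit <- barcode_search(ch, order = 2, method = "ga", pop_size = 10,
                        iterations = 12, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_history(fit, path)
  h <- read.delim(path)
  expect_identical(nrow(h), 12L)
  expect_identical(h$best_fitness, fit$history)
})

test_that("the CLI generates reproducible cohorts", {
  out1 <- withr::local_tempfile(fileext = ".csv")
  out2 <- withr::local_tempfile(fileext = ".csv")
  suppressMessages({
    snpbarcode_cli(c("generate", "--seed", "4", "--n-per-group", "50",
                     "--out", out1))
    snpbarcode_cli(c("generate", "--seed", "4", "--n-per-group", "50",
                     "--out", out2))
  })
  expect_identical(unname(tools::md5sum(out1)), unname(tools::md5sum(out2)))
  df <- read.csv(out1, check.names = FALSE)
  expect_identical(nrow(df), 100L)
  expect_identical(ncol(df), 28L)  # sample_id + label + 26 SNPs
  expect_identical(names(df)[3], "rs2237054")
})

test_that("the CLI search writes report, history and manifest", {
  cohort_csv <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(
    snpbarcode_cli(c("generate", "--seed", "4", "--n-per-group", "200",
                     "--out", cohort_csv)))
  prefix <- file.path(withr::local_tempdir(), "run")
  suppressMessages(
    snpbarcode_cli(c("search", "--algorithm", "htga", "--order", "2",
                     "--cohort", cohort_csv, "--out-prefix", prefix,
                     "--pop-size", "12", "--iterations", "10",
                     "--seed", "2")))
  report <- read.delim(paste0(prefix, "_report.tsv"))
  expect_identical(nrow(report), 2L)  # barcode row + Other row
  manifest <- readLines(paste0(prefix, "_manifest.txt"))
  expect_true(any(grepl("^algorithm: htga$", manifest)))
  expect_true(any(grepl("^seed: 2$", manifest)))
  expect_true(any(grepl("^cohort_md5: [0-9a-f]{32}$", manifest)))
  h <- read.delim(paste0(prefix, "_history.tsv"))
  expect_identical(nrow(h), 10L)

  prefix2 <- file.path(withr::local_tempdir(), "ex")
  suppressMessages(
    snpbarcode_cli(c("search", "--algorithm", "exhaustive", "--order", "1",
                     "--cohort", cohort_csv, "--out-prefix", prefix2)))
  expect_false(file.exists(paste0(prefix2, "_history.tsv")))
  expect_true(file.exists(paste0(prefix2, "_report.tsv")))
})

test_that("CLI config files supply defaults that flags override", {
  cohort_csv <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(
    snpbarcode_cli(c("generate", "--seed", "4", "--n-per-group", "100",
                     "--out", cohort_csv)))
  cfg <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("pop_size: 10", "iterations: 5", "seed: 11"), cfg)
  prefix <- file.path(withr::local_tempdir(), "cfg")
  suppressMessages(
    snpbarcode_cli(c("search", "--algorithm", "ga", "--order", "2",
                     "--cohort", cohort_csv, "--out-prefix", prefix,
                     "--config", cfg, "--iterations", "7")))
  manifest <- readLines(paste0(prefix, "_manifest.txt"))
  expect_true(any(grepl("^pop_size: 10$", manifest)))   # from config
  expect_true(any(grepl("^iterations: 7$", manifest)))  # flag wins
  expect_true(any(grepl("^seed: 11$", manifest)))
})

test_that("the CLI stats subcommand prints association rows", {
  out <- capture.output(
    snpbarcode_cli(c("stats", "--counts", "1179,1309,3821,3691")))
  expect_true(any(grepl("OR 0.870, 95% CI 0.79-0.95, p .003", out,
                        fixed = TRUE)))
  out2 <- capture.output(
    snpbarcode_cli(c("stats", "--counts", "1,1,1,1")))
  expect_true(any(grepl("OR 1.000", out2, fixed = TRUE)))
  out3 <- capture.output(
    snpbarcode_cli(c("stats", "--counts", "5,0,3,2")))
  expect_true(any(grepl("OR N/A", out3, fixed = TRUE)))
})

test_that("CLI errors carry usable diagnostics", {
  expect_error(snpbarcode_cli(character(0)), "usage")
  expect_error(snpbarcode_cli(c("solve")), "unknown subcommand")
  expect_error(snpbarcode_cli(c("generate")), "--out is required")
  expect_error(snpbarcode_cli(c("stats", "--counts", "1,2")),
               "four integers")
  expect_error(snpbarcode_cli(c("stats", "--barcode", "snps=1 genotypes")),
               "stats: give")
  expect_error(snpbarcode_cli(c("generate", "--seed")), "needs a value")
})
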