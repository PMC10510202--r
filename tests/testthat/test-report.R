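small_stab <- function(seed = 5) {
  stability_config(reps_per_size = 200,
                   corridor_method = "mean_relative_width", seed = seed)
}

test_that("the full analysis is deterministic given cohort and seed", {
  co <- ref_cohort(seed = 14)
  r1 <- run_full_analysis(co, stability = small_stab())
  r2 <- run_full_analysis(co, stability = small_stab())
  expect_identical(r1, r2)
})

test_that("report regeneration from recorded provenance is bit-identical", {
  co <- ref_cohort(seed = 14)
  r1 <- run_full_analysis(co, stability = small_stab())
  # rebuild inputs purely from provenance
  cfg <- do.call(stability_config, r1$provenance$stability_config[
    c("reps_per_size", "min_size", "sampling", "corridor_method",
      "corridor_params", "criterion", "band_percentiles", "pos_quantile",
      "seed")])
  r2 <- run_full_analysis(co, templates = r1$provenance$templates,
                          alpha = r1$provenance$alpha,
                          outlier_k = r1$provenance$outlier_k,
                          stability = cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(r1, d1); write_report(r2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("the report carries the study's design shape", {
  co <- ref_cohort(seed = 14)
  r <- run_full_analysis(co, stability = small_stab())
  for (p in protocols()) {
    expect_equal(c(r$omnibus[[p]]$df_between, r$omnibus[[p]]$df_within),
                 c(2L, 194L))
    expect_equal(c(r$diagnosis[[p]]$anova$df_between,
                   r$diagnosis[[p]]$anova$df_within), c(4L, 190L))
    expect_equal(c(r$sex[[p]]$df_between, r$sex[[p]]$df_within), c(3L, 193L))
  }
  expect_equal(nrow(r$percent_diffs), 8)
  expect_length(r$outlier_audit, 4)
  expect_length(r$stability, 4)
  # conclusion string tracks the omnibus p values
  all_p <- vapply(r$omnibus, `[[`, 1, "p_value")
  expect_identical(r$conclusion == "no significant difference",
                   all(all_p >= 0.05))
})

test_that("missing protocol columns and template values are named errors", {
  co <- ref_cohort(seed = 2)
  broken <- co; broken$efield_motor_tES <- NULL
  expect_error(run_full_analysis(broken), "efield_motor_tES")
  tmpl <- default_templates(); tmpl["Ernie", "prefrontal_tES"] <- NA
  expect_error(run_full_analysis(co, templates = tmpl), "template")
})

test_that("a two-diagnosis cohort reduces to the two-group comparison", {
  co <- ref_cohort(seed = 4)
  co2 <- co[co$diagnosis %in% c("healthy", "anxiety"), ]
  r <- run_full_analysis(co2, stability = small_stab())
  a <- r$diagnosis$motor_TMS$anova
  expect_equal(a$df_between, 1L)
  ph <- r$diagnosis$motor_TMS$posthoc
  expect_equal(nrow(ph), 1)
  # algebraic reduction: F = t^2 and the Tukey p equals the two-sided t p
  expect_equal(ph$q_stat^2 / 2, a$f_stat, tolerance = 1e-9)
  expect_equal(ph$p_adj, a$p_value, tolerance = 1e-9)
})

test_that("report files are written and the JSON parses", {
  co <- ref_cohort(seed = 14)
  r <- run_full_analysis(co, stability = small_stab())
  d <- withr::local_tempdir()
  write_report(r, d)
  expect_true(all(file.exists(file.path(d, c(
    "report.json", "report.txt", "descriptives.csv", "anovas.csv",
    "posthoc.csv", "percent_differences.csv",
    paste0("stability_", protocols(), ".csv"))))))
  j <- jsonlite::read_json(file.path(d, "report.json"))
  expect_equal(j$omnibus$motor_TMS$df_within, 194)
  expect_identical(j$conclusion, r$conclusion)
  txt <- readLines(file.path(d, "report.txt"))
  expect_true(any(grepl("Point of stability", txt)))
})

test_that("the command-line wrapper drives the package", {
  cli <- system.file("cli", "efieldstats.R", package = "efieldstats")
  tbl <- system.file("extdata", "reference_motor_tms_diagnosis.csv",
                     package = "efieldstats")
  out <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "anova", "--summaries", shQuote(tbl)),
                 stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("F\\(4, 190\\) = 6.09", out)))

  bad <- suppressWarnings(system2(file.path(R.home("bin"), "Rscript"),
                                  c(cli, "frobnicate"), stdout = TRUE,
                                  stderr = TRUE))
  expect_false(is.null(attr(bad, "status")))
  expect_true(any(grepl("usage", bad)))

  d <- withr::local_tempdir()
  co_path <- file.path(d, "cohort.csv")
  write_cohort(ref_cohort(seed = 3), co_path)
  out2 <- system2(file.path(R.home("bin"), "Rscript"),
                  c(cli, "stability", "--in", shQuote(co_path),
                    "--protocol", "motor_tES", "--reps", "200",
                    "--corridor", "mean_relative_width",
                    "--out", shQuote(file.path(d, "per_size.csv"))),
                  stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("point of stability", out2)))
  ps <- read.csv(file.path(d, "per_size.csv"))
  expect_identical(names(ps)[1:4], c("size", "mean_of_means", "band_lo", "band_hi"))
  expect_equal(nrow(ps), 195)
})
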