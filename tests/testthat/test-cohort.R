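test_that("default cohort has the study's group structure", {
  co <- ref_cohort(seed = 3)
  expect_s3_class(co, "efield_cohort")
  expect_equal(nrow(co), 195)
  expect_equal(as.integer(table(co$diagnosis)[names(diagnoses())]),
               unname(as.integer(diagnoses())))
  expect_equal(sum(co$sex == "male"), 106)
  expect_equal(sum(co$sex == "female"), 89)
  expect_true(all(co$rmt_pct >= 31 & co$rmt_pct <= 78))
  expect_true(all(as.matrix(co[paste0("efield_", protocols())]) > 0))
  expect_equal(co$stim_pct, pmin(1.2 * co$rmt_pct, 100))
  expect_equal(co$didt_As, co$stim_pct / 100 * 150e6)
})

test_that("generation is bit-reproducible given the seed", {
  expect_identical(ref_cohort(seed = 11), ref_cohort(seed = 11))
  expect_false(identical(ref_cohort(seed = 11), ref_cohort(seed = 12)))
})

test_that("zero SDs collapse every subject onto the cell mean", {
  p <- cohort_params(sds = .ref_sds() * 0, seed = 1)
  co <- generate_cohort(p)
  for (pr in protocols()) {
    v <- co[[paste0("efield_", pr)]]
    expect_equal(v, unname(p$means[co$diagnosis, pr]))
  }
})

test_that("direct mode recovers a cell's moments at large n", {
  p <- cohort_params(
    means = matrix(c(85.26, 80.35, 0.347, 0.299), 1,
                   dimnames = list("healthy", protocols())),
    sds = matrix(c(15.54, 14.88, 0.075, 0.064), 1,
                 dimnames = list("healthy", protocols())),
    group_n = c(healthy = 100000L), seed = 5
  )
  v <- generate_cohort(p)$efield_motor_TMS
  expect_lt(abs(mean(v) - 85.26), 0.2)
  expect_lt(abs(sd(v) - 15.54), 0.2)
})

test_that("cohort tables round-trip through delimited text", {
  co <- ref_cohort(seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back, co, tolerance = 1e-9)
  expect_identical(
    readLines(path, n = 1),
    paste0("subject_id,diagnosis,sex,rmt_pct,stim_pct,didt_As,",
           "efield_motor_TMS,efield_prefrontal_TMS,efield_motor_tES,",
           "efield_prefrontal_tES"))
})

test_that("empty cohorts and bad labels are handled explicitly", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- ref_cohort(seed = 1)
  write_cohort(co[0, ], path)
  expect_length(readLines(path), 1)
  expect_equal(nrow(read_cohort(path)), 0)

  bad <- co
  bad$diagnosis[5] <- "psychosis"
  write_cohort(bad, path)
  expect_error(read_cohort(path), "psychosis")
  expect_error(read_cohort(path), "line 6")
})

test_that("mechanistic mode couples TMS fields to dose but not tES", {
  # TMS cell SDs must exceed the dose-driven variance floor (dose CV
  # ~17% here), so use a cell with a comfortably larger CV
  p <- cohort_params(
    means = .ref_means()["healthy", , drop = FALSE],
    sds = .ref_sds()["healthy", , drop = FALSE] * 2,
    group_n = c(healthy = 10000L), mode = "mechanistic", seed = 9
  )
  co <- generate_cohort(p)
  expect_gt(coef(lm(efield_motor_TMS ~ didt_As, data = co))[2], 0)
  expect_gt(cor(co$efield_motor_TMS, co$didt_As), 0.1)
  expect_lt(abs(cor(co$efield_motor_tES, co$rmt_pct)), 0.05)
  expect_lt(abs(cor(co$efield_prefrontal_tES, co$rmt_pct)), 0.05)
  # marginal moments still calibrated (lognormal gain, moment matching)
  expect_lt(abs(mean(co$efield_motor_TMS) - 84.20), 4 * 28.96 / sqrt(10000))
  expect_lt(abs(sd(co$efield_motor_TMS) / 28.96 - 1), 0.05)
  expect_lt(abs(mean(co$efield_motor_tES) - 0.343), 4 * 0.118 / sqrt(10000))
})

test_that("mechanistic calibration refuses impossible cell SDs", {
  m <- .ref_means()["healthy", , drop = FALSE]
  s <- .ref_sds()["healthy", , drop = FALSE]
  s[1, "motor_TMS"] <- 0.001
  p <- cohort_params(means = m, sds = s, group_n = c(healthy = 10L),
                     mode = "mechanistic", seed = 1)
  expect_error(generate_cohort(p), "healthy/motor_TMS")
})

test_that("within-subject protocol fields are correlated via the latent factor", {
  co <- ref_cohort(seed = 21)
  r <- cor(co$efield_motor_TMS, co$efield_prefrontal_TMS)
  expect_gt(r, 0.05)
  co0 <- generate_cohort(cohort_params(latent_loading = 0, seed = 21))
  expect_lt(abs(cor(co0$efield_motor_TMS, co0$efield_prefrontal_TMS)),
            3 / sqrt(195))
})

test_that("cohort parameter files round-trip through YAML", {
  p <- cohort_params(sds = .ref_sds() * 2, seed = 42, mode = "mechanistic",
                     latent_loading = 0.3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_params(p, path)
  p2 <- read_cohort_params(path)
  expect_equal(p2$means, p$means)
  expect_equal(p2$sds, p$sds)
  expect_equal(p2$templates, p$templates)
  expect_identical(p2$group_n, p$group_n)
  expect_identical(p2$mode, p$mode)
  expect_equal(p2$latent_loading, p$latent_loading)
  expect_identical(generate_cohort(p2), generate_cohort(p))
})

test_that("the shipped default config encodes the reference parameterization", {
  path <- system.file("extdata", "default_cohort.yaml", package = "efieldstats")
  p <- read_cohort_params(path)
  expect_equal(p$means, .ref_means())
  expect_equal(p$sds, .ref_sds())
  expect_identical(unname(p$group_n), c(31L, 87L, 31L, 25L, 21L))
  expect_identical(unname(p$sex_n), c(106L, 89L))
})
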