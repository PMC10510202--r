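test_that("subsample means have the exhaustive-subsample identities", {
  x <- c(4, 8, 15, 16, 23, 42)
  expect_equal(subsample_means(x, size = 6, reps = 50, seed = 1),
               rep(mean(x), 50))
  m1 <- subsample_means(x, size = 1, reps = 30000, seed = 2)
  expect_lt(abs(mean(m1) - mean(x)), 3 * sd(x) / sqrt(30000))
  expect_error(subsample_means(x, size = 7, reps = 10), "exceeds")
  expect_identical(subsample_means(x, 3, 100, seed = 5),
                   subsample_means(x, 3, 100, seed = 5))
})

test_that("size-2 subsamples of {1,2,3} hit the three possible means uniformly", {
  reps <- 30000
  m <- subsample_means(c(1, 2, 3), size = 2, reps = reps, seed = 7)
  expect_true(all(m %in% c(1.5, 2.0, 2.5)))
  sigma <- sqrt((1 / 3) * (2 / 3) / reps)
  for (v in c(1.5, 2.0, 2.5))
    expect_lt(abs(mean(m == v) - 1 / 3), 3 * sigma)
})

test_that("with-replacement subsampling is available and unbiased", {
  x <- rnorm(50, 10, 2)
  m <- subsample_means(x, size = 10, reps = 20000,
                       sampling = "with_replacement", seed = 3)
  expect_lt(abs(mean(m) - mean(x)), 4 * sd(x) / sqrt(10 * 20000) * 5)
  expect_silent(subsample_means(x, size = 60, reps = 10,
                                sampling = "with_replacement", seed = 1))
})

test_that("corridor constructions match their hand-computed definitions", {
  cfg <- stability_config()
  expect_equal(as.numeric(build_corridor(1:100, cfg)), c(5.95, 95.05))
  expect_equal(as.numeric(build_corridor(rep(7, 10), cfg)), c(7, 7))
  cfg_w <- stability_config(corridor_method = "mean_relative_width",
                            corridor_params = list(relative_width = 0.05))
  x <- exact_moments(195, 85.26, 15.54)
  expect_equal(as.numeric(build_corridor(x, cfg_w)), c(80.997, 89.523),
               tolerance = 1e-9)
  cfg_ci <- stability_config(corridor_method = "mean_ci")
  expect_equal(as.numeric(build_corridor(x, cfg_ci)),
               85.26 + c(-1, 1) * qnorm(0.975) * 15.54 / sqrt(195),
               tolerance = 1e-9)
})

test_that("constant data is stable from the smallest size under any criterion", {
  x <- rep(5, 40)
  for (crit in c("band_within_corridor", "trajectory_quantile")) {
    for (meth in c("sample_percentile", "mean_relative_width")) {
      r <- point_of_stability(x, stability_config(
        reps_per_size = 50, criterion = crit, corridor_method = meth, seed = 1))
      expect_equal(r$pos, 1L)
      expect_true(r$reached)
    }
  }
})

test_that("the band collapses at the full sample size without replacement", {
  x <- rnorm(60, 85, 15)
  r <- point_of_stability(x, stability_config(
    reps_per_size = 300, corridor_method = "mean_relative_width", seed = 2))
  last <- r$per_size[nrow(r$per_size), ]
  expect_equal(last$band_hi - last$band_lo, 0)
  expect_equal(last$mean_of_means, mean(x))
  expect_true(r$reached)  # full mean is inside its own relative corridor
  expect_true(r$pos >= 1 && r$pos <= 60)
})

test_that("rescaling the data leaves the relative-width pos unchanged", {
  x <- exact_moments(120, 85, 15, seed = 6)
  cfg <- stability_config(reps_per_size = 500,
                          corridor_method = "mean_relative_width", seed = 11)
  r1 <- point_of_stability(x, cfg)
  r2 <- point_of_stability(1000 * x, cfg)
  expect_identical(r1$pos, r2$pos)
  expect_equal(r2$per_size$band_lo, 1000 * r1$per_size$band_lo)
})

test_that("widening the corridor never delays the point of stability", {
  x <- exact_moments(195, 85.26, 15.54, seed = 3)
  for (seed in 1:6) {
    narrow <- point_of_stability(x, stability_config(
      reps_per_size = 500, corridor_method = "mean_relative_width",
      corridor_params = list(relative_width = 0.03), seed = seed))
    wide <- point_of_stability(x, stability_config(
      reps_per_size = 500, corridor_method = "mean_relative_width",
      corridor_params = list(relative_width = 0.06), seed = seed))
    expect_lte(wide$pos, narrow$pos)
  }
})

test_that("stability streams are derived per size from the master seed", {
  x <- rnorm(50, 10, 3)
  cfg <- stability_config(reps_per_size = 200,
                          corridor_method = "mean_relative_width", seed = 9)
  r1 <- point_of_stability(x, cfg)
  r2 <- point_of_stability(x, cfg)
  expect_identical(r1, r2)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(point_of_stability(x, cfg2)$per_size, r1$per_size))
})

test_that("trajectory criterion reports the configured quantile of entry times", {
  x <- exact_moments(100, 85, 15, seed = 4)
  cfg <- stability_config(reps_per_size = 400, criterion = "trajectory_quantile",
                          corridor_method = "mean_relative_width", seed = 5)
  r <- point_of_stability(x, cfg)
  expect_true(r$reached)
  expect_true(r$pos >= 1 && r$pos <= 100)
  cfg50 <- cfg; cfg50$pos_quantile <- 0.5
  r50 <- point_of_stability(x, cfg50)
  expect_lte(r50$pos, r$pos)
})

test_that("doubling the rep count moves pos only within the documented jitter", {
  co <- ref_cohort(seed = 30)
  x <- co$efield_motor_TMS
  jitter <- vapply(1:20, function(seed) {
    p1 <- point_of_stability(x, stability_config(
      reps_per_size = 10000, corridor_method = "mean_relative_width",
      seed = seed))$pos
    p2 <- point_of_stability(x, stability_config(
      reps_per_size = 20000, corridor_method = "mean_relative_width",
      seed = seed + 1000))$pos
    abs(p1 - p2)
  }, 1)
  expect_lte(max(jitter), 3)
})
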