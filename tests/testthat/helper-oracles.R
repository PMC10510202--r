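# Independent oracles and fixture builders used across the suite.

# F statistic via stats::aov, as an implementation-independent route.
oracle_f_aov <- function(values_by_group) {
  df <- data.frame(
    y = unlist(values_by_group, use.names = FALSE),
    g = factor(rep(names(values_by_group) %||% seq_along(values_by_group),
                   lengths(values_by_group)))
  )
  summary(stats::aov(y ~ g, data = df))[[1]]$`F value`[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vector with exact sample mean and SD.
exact_moments <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  base <- rnorm(n)
  as.numeric(mean + sd * scale(base))
}

# Closed-form normal approximation of the band-within-corridor point of
# stability for a mean_relative_width corridor: the 5-95 percentile band
# of without-replacement subsample means has half-width about
# z_0.95 * sd * sqrt((N - s) / (N * s)).
approx_pos_normal <- function(n, mean, sd, w) {
  s <- 1:n
  half <- qnorm(0.95) * sd * sqrt((n - s) / (n * s))
  s[which(half <= w * mean)[1]]
}

# Reference-parameterized cohort at a given seed.
ref_cohort <- function(seed, ...) {
  generate_cohort(cohort_params(seed = seed, ...))
}
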