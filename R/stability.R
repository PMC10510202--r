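#' Configuration of the point-of-stability analysis
#'
#' Controls the permutation subsampling scheme, the corridor of stability,
#' and the stopping criterion. Defaults mirror the reference procedure:
#' 10,000 independent subsamples per size, sizes 1..N, sampling without
#' replacement, corridor between the 5th and 95th percentiles of the full
#' sample, and the point of stability defined as the smallest size whose
#' 5-95 percentile band of subsample means lies inside the corridor for
#' that and every larger size.
#'
#' Three corridor constructions are implemented because the percentile
#' reading of the corridor is scale-generous (a size-1 subsample already
#' falls inside a P5-P95 value corridor 90% of the time):
#' `"sample_percentile"` (the literal reading), `"mean_relative_width"`
#' (mean * (1 -/+ w); the reading whose point-of-stability magnitude
#' matches published several-tens values), and `"mean_ci"`
#' (mean -/+ z * sd / sqrt(N)).
#'
#' @param reps_per_size Subsamples drawn per size (default 10000).
#' @param min_size,max_size Size range (defaults 1 and N).
#' @param sampling `"without_replacement"` (default; subsamples of a fixed
#'   cohort cannot repeat a subject) or `"with_replacement"`.
#' @param corridor_method One of `"sample_percentile"`,
#'   `"mean_relative_width"`, `"mean_ci"`.
#' @param corridor_params List of method-specific parameters:
#'   `percentiles` (default `c(5, 95)`), `relative_width` (default 0.05),
#'   `ci_level` (default 0.95). Unused entries are ignored.
#' @param criterion `"band_within_corridor"` (default): per-size
#'   percentile band of independent subsample means must sit inside the
#'   corridor from the candidate size up to `max_size`.
#'   `"trajectory_quantile"`: per permutation of the subjects, running
#'   means define an individual point of stability (entry into the
#'   corridor without later exit); the reported value is the
#'   `pos_quantile` quantile over permutations.
#' @param band_percentiles Percentile band of subsample means (default
#'   `c(5, 95)`).
#' @param pos_quantile Quantile of per-trajectory points of stability
#'   reported under the trajectory criterion (default 0.95).
#' @param seed Master seed. One stream per subsample size is derived from
#'   it, so results are invariant to evaluation order.
#' @return Object of class `stability_config`.
#' @export
stability_config <- function(reps_per_size = 10000L, min_size = 1L,
                             max_size = NULL,
                             sampling = c("without_replacement",
                                          "with_replacement"),
                             corridor_method = c("sample_percentile",
                                                 "mean_relative_width",
                                                 "mean_ci"),
                             corridor_params = list(),
                             criterion = c("band_within_corridor",
                                           "trajectory_quantile"),
                             band_percentiles = c(5, 95),
                             pos_quantile = 0.95, seed = 1L) {
  defaults <- list(percentiles = c(5, 95), relative_width = 0.05,
                   ci_level = 0.95)
  corridor_params <- utils::modifyList(defaults, corridor_params)
  if (diff(corridor_params$percentiles) <= 0 || diff(band_percentiles) <= 0)
    stop("percentile bounds must be ordered")
  if (reps_per_size < 1L) stop("reps_per_size must be >= 1")
  if (min_size < 1L || (!is.null(max_size) && max_size < min_size))
    stop("need 1 <= min_size <= max_size")
  structure(list(
    reps_per_size = as.integer(reps_per_size),
    min_size = as.integer(min_size),
    max_size = if (is.null(max_size)) NULL else as.integer(max_size),
    sampling = match.arg(sampling),
    corridor_method = match.arg(corridor_method),
    corridor_params = corridor_params,
    criterion = match.arg(criterion),
    band_percentiles = as.numeric(band_percentiles),
    pos_quantile = pos_quantile,
    seed = as.integer(seed)
  ), class = "stability_config")
}

# Derived stream seed for one subsample size (0 = the trajectory stream),
# kept inside 32-bit range.
.stream_seed <- function(seed, size) {
  as.integer((as.double(seed) + 7919 * (as.double(size) + 1)) %% 2147483647)
}

#' Means of random subsamples
#'
#' Draws `reps` independent subsamples of `size` values and returns their
#' means. Deterministic given `seed`. Without replacement at `size ==
#' length(values)` every subsample is the full sample, and the full-sample
#' mean is returned exactly.
#'
#' @param values Numeric vector.
#' @param size Subsample size (<= `length(values)` without replacement).
#' @param reps Number of subsamples.
#' @param sampling `"without_replacement"` (default) or
#'   `"with_replacement"`.
#' @param seed Optional seed set before drawing.
#' @return Numeric vector of `reps` subsample means.
#' @export
#' @examples
#' subsample_means(1:10, size = 4, reps = 5, seed = 1)
subsample_means <- function(values, size, reps,
                            sampling = c("without_replacement",
                                         "with_replacement"),
                            seed = NULL) {
  sampling <- match.arg(sampling)
  n <- length(values)
  if (size < 1) stop("size must be >= 1")
  if (sampling == "without_replacement" && size > n)
    stop(sprintf("size %d exceeds n = %d for sampling without replacement",
                 size, n))
  if (!is.null(seed)) set.seed(seed)
  if (sampling == "without_replacement" && size == n)
    return(rep(sum(values) / n, reps))
  cpp_subsample_means(as.numeric(values), as.integer(size),
                      as.integer(reps), sampling == "with_replacement")
}

#' Corridor of stability
#'
#' Builds the interval against which subsample means are judged stable.
#' Percentiles use linear interpolation between closest ranks
#' (`quantile(type = 7)`); this matters for small samples and is recorded
#' in the result metadata.
#'
#' @param values Numeric vector (length >= 2 unless constant).
#' @param config A [stability_config()].
#' @return Named numeric `c(lower, upper)` with attribute `method`.
#' @export
#' @examples
#' build_corridor(1:100, stability_config())  # (5.95, 95.05)
build_corridor <- function(values, config = stability_config()) {
  stopifnot(inherits(config, "stability_config"))
  if (length(values) < 2) stop("need at least 2 values")
  cp <- config$corridor_params
  bounds <- switch(config$corridor_method,
    sample_percentile = stats::quantile(values, cp$percentiles / 100,
                                        type = 7, names = FALSE),
    mean_relative_width = mean(values) * c(1 - cp$relative_width,
                                           1 + cp$relative_width),
    mean_ci = {
      z <- stats::qnorm(1 - (1 - cp$ci_level) / 2)
      mean(values) + c(-1, 1) * z * stats::sd(values) / sqrt(length(values))
    }
  )
  bounds <- sort(bounds)
  if (bounds[1] == bounds[2] && stats::sd(values) > 0)
    stop("degenerate corridor on non-constant data")
  structure(c(lower = bounds[1], upper = bounds[2]),
            method = config$corridor_method)
}

#' Point of stability of a group mean
#'
#' Estimates how many subjects are needed before the group-mean estimate
#' becomes stable: the smallest subsample size at which subsample means
#' enter the corridor of stability and do not leave it at any larger size
#' (up to `max_size`). See [stability_config()] for the two criteria and
#' three corridor constructions.
#'
#' @param values Numeric vector of per-subject outcomes (V/m).
#' @param config A [stability_config()].
#' @return Object of class `stability_result`: `corridor`, a per-size
#'   table (`size`, `mean_of_means`, `band_lo`, `band_hi`,
#'   `inside_corridor`), `pos` (NA when never stable), `reached`, and a
#'   config echo.
#' @export
#' @examples
#' x <- rnorm(60, 85, 15)
#' r <- point_of_stability(x, stability_config(
#'   reps_per_size = 200, corridor_method = "mean_relative_width", seed = 1))
#' r$pos
point_of_stability <- function(values, config = stability_config()) {
  stopifnot(inherits(config, "stability_config"))
  n <- length(values)
  max_size <- if (is.null(config$max_size)) n else config$max_size
  if (config$sampling == "without_replacement" && max_size > n)
    stop("max_size exceeds the number of values")
  sizes <- config$min_size:max_size
  corridor <- build_corridor(values, config)
  bp <- config$band_percentiles / 100

  if (config$criterion == "band_within_corridor") {
    mom <- band_lo <- band_hi <- numeric(length(sizes))
    for (i in seq_along(sizes)) {
      mns <- subsample_means(values, sizes[i], config$reps_per_size,
                             config$sampling,
                             seed = .stream_seed(config$seed, sizes[i]))
      mom[i] <- mean(mns)
      qs <- stats::quantile(mns, bp, type = 7, names = FALSE)
      band_lo[i] <- qs[1]; band_hi[i] <- qs[2]
    }
    inside <- band_lo >= corridor[["lower"]] & band_hi <= corridor[["upper"]]
    stable_from_here <- rev(cumprod(rev(inside))) > 0
    pos <- if (any(stable_from_here)) sizes[which(stable_from_here)[1]] else NA_integer_
    per_size <- data.frame(size = sizes, mean_of_means = mom,
                           band_lo = band_lo, band_hi = band_hi,
                           inside_corridor = inside)
  } else {
    set.seed(.stream_seed(config$seed, 0L))
    reps <- config$reps_per_size
    run <- matrix(NA_real_, reps, n)
    for (r in seq_len(reps)) {
      perm <- if (config$sampling == "with_replacement")
        values[sample.int(n, n, replace = TRUE)]
      else values[sample.int(n)]
      run[r, ] <- cumsum(perm) / seq_len(n)
    }
    run <- run[, sizes, drop = FALSE]
    ins <- run >= corridor[["lower"]] & run <= corridor[["upper"]]
    traj_pos <- apply(ins, 1, function(v) {
      out <- which(!v)
      if (!length(out)) return(sizes[1])
      if (out[length(out)] == length(v)) return(NA_integer_)
      sizes[out[length(out)] + 1L]
    })
    pos_q <- stats::quantile(ifelse(is.na(traj_pos), Inf, traj_pos),
                             config$pos_quantile, type = 1, names = FALSE)
    pos <- if (is.finite(pos_q)) as.integer(pos_q) else NA_integer_
    per_size <- data.frame(
      size = sizes,
      mean_of_means = colMeans(run),
      band_lo = apply(run, 2, stats::quantile, bp[1], type = 7),
      band_hi = apply(run, 2, stats::quantile, bp[2], type = 7)
    )
    per_size$inside_corridor <- per_size$band_lo >= corridor[["lower"]] &
      per_size$band_hi <= corridor[["upper"]]
  }

  structure(list(
    corridor = corridor, per_size = per_size,
    pos = pos, reached = !is.na(pos),
    n = n, full_mean = mean(values),
    percentile_definition = "linear interpolation (quantile type 7)",
    config = config
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Point-of-stability analysis (n = %d, %s corridor, %s criterion)\n",
              x$n, x$config$corridor_method, x$config$criterion))
  cat(sprintf("  corridor: [%.4g, %.4g]; full-sample mean %.4g\n",
              x$corridor[["lower"]], x$corridor[["upper"]], x$full_mean))
  if (x$reached) cat(sprintf("  point of stability: n = %d\n", x$pos))
  else cat("  point of stability: not reached within the size range\n")
  invisible(x)
}

#' @export
summary.stability_result <- function(object, ...) {
  print(object)
  cat(sprintf("  sizes %d..%d, %d subsamples per size, sampling %s, seed %d\n",
              min(object$per_size$size), max(object$per_size$size),
              object$config$reps_per_size, object$config$sampling,
              object$config$seed))
  cat(sprintf("  percentile rule: %s\n", object$percentile_definition))
  invisible(object)
}

#' Plot a point-of-stability analysis
#'
#' Subsample-mean percentile band versus subsample size, with the corridor
#' of stability and a vertical line at the point of stability.
#'
#' @param x A `stability_result`.
#' @param main Plot title.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stability_result <- function(x, main = "Point of stability", ...) {
  ps <- x$per_size
  ylim <- range(ps$band_lo, ps$band_hi, x$corridor)
  graphics::plot(ps$size, ps$mean_of_means, type = "n", ylim = ylim,
                 xlab = "subsample size", ylab = "subsample mean (V/m)",
                 main = main, ...)
  graphics::polygon(c(ps$size, rev(ps$size)), c(ps$band_lo, rev(ps$band_hi)),
                    col = "grey85", border = NA)
  graphics::lines(ps$size, ps$mean_of_means, lwd = 1.5)
  graphics::abline(h = x$corridor, lty = 2, col = "steelblue")
  if (x$reached) graphics::abline(v = x$pos, lty = 1, col = "firebrick")
  invisible(x)
}
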