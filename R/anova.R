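#' Group sufficient statistics
#'
#' @param label Group labels.
#' @param n Group sizes (>= 1).
#' @param mean Group means (V/m).
#' @param sd Group SDs; ignored (and taken as 0) for singleton groups such
#'   as template head models.
#' @return Data frame with columns `label`, `n`, `mean`, `sd`.
#' @export
#' @examples
#' group_summary(c("individuals", "MNI152", "Ernie"),
#'               n = c(195, 1, 1), mean = c(85.26, 78.16, 81.46),
#'               sd = c(15.54, 0, 0))
group_summary <- function(label, n, mean, sd = 0) {
  df <- data.frame(label = as.character(label), n = as.integer(n),
                   mean = as.numeric(mean), sd = as.numeric(sd),
                   stringsAsFactors = FALSE)
  if (any(df$n < 1L)) stop("group sizes must be >= 1")
  df$sd[df$n == 1L] <- 0
  if (any(df$sd < 0 | !is.finite(df$sd)) || any(!is.finite(df$mean)))
    stop("group means must be finite and SDs >= 0")
  df
}

#' One-way ANOVA from group sufficient statistics
#'
#' Computes the one-way fixed-effects ANOVA directly from per-group
#' (n, mean, SD). Singleton groups (n = 1) are legal and contribute zero
#' within-group sum of squares and zero within degrees of freedom; this is
#' how template head models enter the omnibus comparison against an
#' individual-scan group (e.g. 195 individuals + 2 templates gives
#' df = (2, 194)).
#'
#' @param groups Data frame as from [group_summary()] (columns `label`,
#'   `n`, `mean`, `sd`).
#' @return Object of class `efield_anova`: F statistic, degrees of
#'   freedom, p value, partial eta squared
#'   (`SS_between / (SS_between + SS_within)`), and sums of squares.
#' @seealso [anova_from_raw()], [tukey_kramer()]
#' @export
#' @examples
#' g <- group_summary(c("individuals", "MNI152", "Ernie"),
#'                    n = c(195, 1, 1), mean = c(85.26, 78.16, 81.46),
#'                    sd = c(15.54, 0, 0))
#' anova_from_summaries(g)
anova_from_summaries <- function(groups) {
  groups <- group_summary(groups$label, groups$n, groups$mean, groups$sd)
  k <- nrow(groups)
  if (k < 2) stop("need at least 2 groups")
  n <- groups$n; m <- groups$mean; s <- groups$sd
  df_within <- sum(n - 1L)
  if (df_within < 1L)
    stop("within-group variance undefined: all groups are singletons")
  grand <- sum(n * m) / sum(n)
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1L) * s^2)
  df_between <- k - 1L
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  f <- ms_between / ms_within
  structure(list(
    f_stat = f, df_between = df_between, df_within = df_within,
    p_value = stats::pf(f, df_between, df_within, lower.tail = FALSE),
    eta_p2 = if (ss_between + ss_within > 0) ss_between / (ss_between + ss_within) else 0,
    ss_between = ss_between, ss_within = ss_within,
    ms_within = ms_within, grand_mean = grand, groups = groups
  ), class = "efield_anova")
}

#' One-way ANOVA from raw values
#'
#' Same model as [anova_from_summaries()], computed from the raw values by
#' the classical sum-of-squares decomposition. The two routes agree to
#' numerical precision; the raw route serves cohort-level data, the
#' summary route serves published tables.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @return Object of class `efield_anova`.
#' @export
#' @examples
#' anova_from_raw(list(a = c(1, 2, 3), b = c(4, 5, 6)))
anova_from_raw <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2)
    stop("need at least 2 groups")
  n <- vapply(values_by_group, length, 1L)
  if (any(n == 0L)) stop("every group needs at least one value")
  if (sum(n) <= length(n)) stop("need more observations than groups")
  labels <- names(values_by_group)
  if (is.null(labels)) labels <- paste0("group", seq_along(values_by_group))
  m <- vapply(values_by_group, mean, 1)
  grand <- sum(unlist(values_by_group)) / sum(n)
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum(vapply(seq_along(values_by_group), function(i)
    sum((values_by_group[[i]] - m[i])^2), 1))
  df_between <- length(n) - 1L
  df_within <- sum(n - 1L)
  f <- (ss_between / df_between) / (ss_within / df_within)
  s <- vapply(values_by_group, function(v) if (length(v) > 1) stats::sd(v) else 0, 1)
  structure(list(
    f_stat = f, df_between = df_between, df_within = df_within,
    p_value = stats::pf(f, df_between, df_within, lower.tail = FALSE),
    eta_p2 = if (ss_between + ss_within > 0) ss_between / (ss_between + ss_within) else 0,
    ss_between = ss_between, ss_within = ss_within,
    ms_within = ss_within / df_within, grand_mean = grand,
    groups = group_summary(labels, n, m, s)
  ), class = "efield_anova")
}

#' @export
print.efield_anova <- function(x, digits = 2, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.*f, p = %.*f, eta_p^2 = %.3f\n",
              x$df_between, x$df_within, digits, x$f_stat, digits,
              x$p_value, x$eta_p2))
  invisible(x)
}

#' @export
summary.efield_anova <- function(object, ...) {
  cat("Groups:\n")
  print(object$groups, row.names = FALSE)
  cat(sprintf("SS_between = %.6g (df %d), SS_within = %.6g (df %d)\n",
              object$ss_between, object$df_between,
              object$ss_within, object$df_within))
  print(object)
  invisible(object)
}

#' Tukey-Kramer all-pairs post-hoc comparisons
#'
#' Studentized-range post hocs from group sufficient statistics,
#' generalized to unequal group sizes (Tukey-Kramer): for each pair,
#' `q = |mean_a - mean_b| / sqrt((MSw / 2) (1/n_a + 1/n_b))`, with the
#' adjusted p value from the studentized-range distribution on
#' (k, df_within). Intended for the diagnosis factor; singleton template
#' groups must be excluded first.
#'
#' @param groups Data frame as for [anova_from_summaries()]; at least 2
#'   groups (with 2 the procedure reduces to the two-group t comparison),
#'   each with n >= 2.
#' @param alpha Two-tailed significance level (default 0.05).
#' @return Data frame of class `tukey_kramer` with one row per pair:
#'   `group_a`, `group_b`, `diff` (mean_a - mean_b), `q_stat`, `p_adj`,
#'   `significant`.
#' @export
#' @examples
#' tukey_kramer(reference_summaries("motor_TMS", "diagnosis"))
tukey_kramer <- function(groups, alpha = 0.05) {
  groups <- group_summary(groups$label, groups$n, groups$mean, groups$sd)
  if (nrow(groups) < 2) stop("need at least 2 groups for Tukey-Kramer")
  if (any(groups$n < 2))
    stop("singleton groups are not comparable post hoc; exclude template groups")
  fit <- anova_from_summaries(groups)
  k <- nrow(groups)
  pairs <- utils::combn(k, 2)
  res <- data.frame(
    group_a = groups$label[pairs[1, ]],
    group_b = groups$label[pairs[2, ]],
    stringsAsFactors = FALSE
  )
  res$diff <- groups$mean[pairs[1, ]] - groups$mean[pairs[2, ]]
  se <- sqrt(fit$ms_within / 2 *
               (1 / groups$n[pairs[1, ]] + 1 / groups$n[pairs[2, ]]))
  res$q_stat <- abs(res$diff) / se
  res$p_adj <- stats::ptukey(res$q_stat, nmeans = k, df = fit$df_within,
                             lower.tail = FALSE)
  res$significant <- res$p_adj < alpha
  structure(res, class = c("tukey_kramer", "data.frame"),
            alpha = alpha, df_within = fit$df_within, nmeans = k)
}

#' @export
print.tukey_kramer <- function(x, digits = 3, ...) {
  cat(sprintf("Tukey-Kramer post hocs (%d groups, df = %d, alpha = %g)\n",
              attr(x, "nmeans"), attr(x, "df_within"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df$diff <- round(df$diff, digits)
  df$q_stat <- round(df$q_stat, digits)
  df$p_adj <- round(df$p_adj, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Template-versus-group percent difference
#'
#' How much lower (positive result) or higher (negative) a template head
#' model's E-field is than the group mean, in percent of the group mean:
#' `(group_mean - template_value) / group_mean * 100`.
#'
#' @param template_value Template E-field, V/m.
#' @param group_mean Group-average E-field, V/m; must be > 0.
#' @return Percent difference (positive = template lower than the group).
#' @export
#' @examples
#' percent_difference(78.16, 85.26)  # ~8.3% lower
percent_difference <- function(template_value, group_mean) {
  if (any(!is.finite(group_mean)) || any(group_mean <= 0))
    stop("group_mean must be > 0")
  (group_mean - template_value) / group_mean * 100
}

#' Count values beyond k standard deviations
#'
#' The +/- k SD audit: how many values lie strictly more than `k` sample
#' SDs from the sample mean (mean and SD computed from the same values).
#' With k = 2 this approximates a 95% normal-range audit.
#'
#' @param values Numeric vector (length >= 2).
#' @param k Number of SDs (default 2).
#' @param labels Optional labels for the flagged values (default names or
#'   indices).
#' @return List with `count`, `labels`, and the flagging `bounds`.
#' @export
#' @examples
#' outliers_beyond_k_sd(c(rep(0, 9), 10))
outliers_beyond_k_sd <- function(values, k = 2, labels = NULL) {
  if (length(values) < 2) stop("need at least 2 values")
  if (!is.finite(k) || k <= 0) stop("k must be > 0")
  if (is.null(labels))
    labels <- if (!is.null(names(values))) names(values)
              else as.character(seq_along(values))
  m <- mean(values); s <- stats::sd(values)
  out <- abs(values - m) > k * s
  list(count = sum(out), labels = labels[out],
       bounds = c(lower = m - k * s, upper = m + k * s))
}
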