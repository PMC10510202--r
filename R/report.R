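# Per-protocol display precision: V/m to 2 decimals for TMS-scale values,
# 3 decimals for sub-V/m tES values.
.vm_digits <- function(x) if (max(abs(x), na.rm = TRUE) < 1) 3L else 2L

.efield_col <- function(protocol) paste0("efield_", protocol)

#' Full group-level dosimetry analysis
#'
#' Runs the complete pipeline on a cohort table: descriptives, four
#' omnibus template-comparison ANOVAs (individuals plus two singleton
#' template head models), four diagnosis ANOVAs with Tukey-Kramer post
#' hocs, four sex ANOVAs (men, women, two templates), template-vs-group
#' percent differences, the +/- 2 SD outlier audit, and four
#' point-of-stability analyses.
#'
#' @param cohort An `efield_cohort` data frame (see [generate_cohort()],
#'   [read_cohort()]).
#' @param templates 2 x 4 template value matrix as from
#'   [default_templates()].
#' @param alpha Significance level for every test (default 0.05,
#'   two-tailed). No multiplicity correction is applied across the twelve
#'   ANOVAs.
#' @param outlier_k SD multiplier of the outlier audit (default 2).
#' @param stability A [stability_config()]; each protocol gets a seed
#'   stream derived from its master seed.
#' @return Object of class `efield_report`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_params(seed = 7))
#' rep <- run_full_analysis(co,
#'   stability = stability_config(reps_per_size = 200, seed = 7))
#' print(rep)
run_full_analysis <- function(cohort, templates = default_templates(),
                              alpha = 0.05, outlier_k = 2,
                              stability = stability_config()) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0)
  prot <- protocols()
  miss <- setdiff(.efield_col(prot), names(cohort))
  if (length(miss))
    stop("cohort is missing protocol columns: ", paste(miss, collapse = ", "))
  if (!all(prot %in% colnames(templates)) ||
      !all(c("MNI152", "Ernie") %in% rownames(templates)))
    stop("missing template value: need rows MNI152/Ernie for all 4 protocols")
  if (any(!is.finite(templates[c("MNI152", "Ernie"), prot])))
    stop("missing template value: all 8 template E-fields must be finite")

  desc <- do.call(rbind, lapply(prot, function(p) {
    v <- cohort[[.efield_col(p)]]
    by_dx <- split(v, cohort$diagnosis)
    by_sex <- split(v, cohort$sex)
    rbind(
      data.frame(population = "transdiagnostic", protocol = p,
                 n = length(v), mean = mean(v), sd = stats::sd(v)),
      data.frame(population = names(by_dx), protocol = p,
                 n = lengths(by_dx), mean = vapply(by_dx, mean, 1),
                 sd = vapply(by_dx, stats::sd, 1)),
      data.frame(population = names(by_sex), protocol = p,
                 n = lengths(by_sex), mean = vapply(by_sex, mean, 1),
                 sd = vapply(by_sex, stats::sd, 1)),
      data.frame(population = rownames(templates), protocol = p,
                 n = 1L, mean = templates[, p], sd = NA_real_)
    )
  }))
  rownames(desc) <- NULL

  omnibus <- lapply(prot, function(p) {
    anova_from_raw(list(
      individual = cohort[[.efield_col(p)]],
      MNI152 = templates["MNI152", p],
      Ernie = templates["Ernie", p]
    ))
  })
  names(omnibus) <- prot

  diagnosis <- lapply(prot, function(p) {
    by_dx <- split(cohort[[.efield_col(p)]], cohort$diagnosis)
    fit <- anova_from_raw(by_dx)
    list(anova = fit, posthoc = tukey_kramer(fit$groups, alpha = alpha))
  })
  names(diagnosis) <- prot

  sex <- lapply(prot, function(p) {
    by_sex <- split(cohort[[.efield_col(p)]], cohort$sex)
    anova_from_raw(c(by_sex, list(MNI152 = templates["MNI152", p],
                                  Ernie = templates["Ernie", p])))
  })
  names(sex) <- prot

  pd <- expand.grid(template = rownames(templates), protocol = prot,
                    stringsAsFactors = FALSE)
  pd$template_value <- templates[cbind(pd$template, pd$protocol)]
  pd$group_mean <- vapply(pd$protocol,
                          function(p) mean(cohort[[.efield_col(p)]]), 1)
  pd$percent_lower <- percent_difference(pd$template_value, pd$group_mean)

  audit <- lapply(prot, function(p)
    outliers_beyond_k_sd(cohort[[.efield_col(p)]], k = outlier_k,
                         labels = cohort$subject_id))
  names(audit) <- prot

  stab <- lapply(seq_along(prot), function(k) {
    cfg <- stability
    cfg$seed <- as.integer((as.double(stability$seed) + 1000003 * k) %% 2147483647)
    point_of_stability(cohort[[.efield_col(prot[k])]], cfg)
  })
  names(stab) <- prot

  all_p <- vapply(omnibus, function(a) a$p_value, 1)
  structure(list(
    descriptives = desc, omnibus = omnibus, diagnosis = diagnosis,
    sex = sex, percent_diffs = pd, outlier_audit = audit,
    stability = stab,
    conclusion = if (all(all_p >= alpha))
      "no significant difference" else "significant difference detected",
    template_note = paste(
      "Motor-TMS template attribution is ambiguous in the reference",
      "publication (summary table vs. results text swap MNI-152 and",
      "Ernie); omnibus F statistics are invariant to the swap, percent",
      "differences are not."),
    provenance = list(
      alpha = alpha, outlier_k = outlier_k,
      stability_config = unclass(stability),
      templates = templates, n = nrow(cohort),
      package_version = as.character(utils::packageVersion("efieldstats"))
    )
  ), class = "efield_report")
}

#' @export
print.efield_report <- function(x, ...) {
  prot <- protocols()
  cat("Group-level E-field dosimetry report\n")
  cat(sprintf("N = %d subjects; alpha = %g\n\n", x$provenance$n,
              x$provenance$alpha))

  cat("E-field means (SD), V/m:\n")
  pops <- unique(x$descriptives$population)
  wide <- sapply(prot, function(p) {
    d <- x$descriptives[x$descriptives$protocol == p, ]
    d <- d[match(pops, d$population), ]
    dg <- .vm_digits(d$mean)
    ifelse(is.na(d$sd), sprintf("%.*f", dg, d$mean),
           sprintf("%.*f (%.*f)", dg, d$mean, dg, d$sd))
  })
  rownames(wide) <- pops
  print(as.data.frame(wide))

  cat("\nOmnibus (individuals vs. MNI-152 vs. Ernie):\n")
  for (p in prot) {
    a <- x$omnibus[[p]]
    cat(sprintf("  %-15s F(%d, %d) = %.2f, p = %.2f, eta_p^2 = %.3f\n",
                p, a$df_between, a$df_within, a$f_stat, a$p_value, a$eta_p2))
  }
  cat(sprintf("  conclusion: %s\n", x$conclusion))

  cat("\nDiagnosis ANOVAs:\n")
  for (p in prot) {
    a <- x$diagnosis[[p]]$anova
    sig <- x$diagnosis[[p]]$posthoc
    sig <- sig[sig$significant, ]
    cat(sprintf("  %-15s F(%d, %d) = %.2f, p = %.2f, eta_p^2 = %.3f\n",
                p, a$df_between, a$df_within, a$f_stat, a$p_value, a$eta_p2))
    if (nrow(sig))
      cat(sprintf("    Tukey-significant: %s\n",
                  paste(sig$group_a, sig$group_b, sep = "-", collapse = ", ")))
  }

  cat("\nSex ANOVAs (men, women, templates):\n")
  for (p in prot) {
    a <- x$sex[[p]]
    cat(sprintf("  %-15s F(%d, %d) = %.2f, p = %.2f, eta_p^2 = %.3f\n",
                p, a$df_between, a$df_within, a$f_stat, a$p_value, a$eta_p2))
  }

  cat("\nTemplate vs. group percent differences (positive = template lower):\n")
  for (i in seq_len(nrow(x$percent_diffs)))
    cat(sprintf("  %-8s %-15s %6.1f%%\n", x$percent_diffs$template[i],
                x$percent_diffs$protocol[i], x$percent_diffs$percent_lower[i]))

  cat(sprintf("\nOutlier audit (+/- %g SD): %s\n", x$provenance$outlier_k,
              paste(sprintf("%s: %d", prot,
                            vapply(x$outlier_audit, `[[`, 1L, "count")),
                    collapse = ", ")))

  cat("\nPoint of stability:\n")
  for (p in prot) {
    s <- x$stability[[p]]
    cat(sprintf("  %-15s %s (corridor [%.4g, %.4g], %s)\n", p,
                if (s$reached) sprintf("n = %d", s$pos) else "not reached",
                s$corridor[["lower"]], s$corridor[["upper"]],
                s$config$corridor_method))
  }
  cat(sprintf("\nNote: %s\n", x$template_note))
  cat("No multiple-testing correction applied across the twelve ANOVAs.\n")
  invisible(x)
}

#' Plot pieces of a dosimetry report
#'
#' `which = "means"` draws per-population mean +/- SD bars for one
#' protocol; `which = "stability"` draws the subsample-mean band with the
#' corridor and the point of stability.
#'
#' @param x An `efield_report`.
#' @param which `"means"` or `"stability"`.
#' @param protocol One of [protocols()].
#' @param ... Passed on to the underlying plot.
#' @export
plot.efield_report <- function(x, which = c("means", "stability"),
                               protocol = protocols(), ...) {
  which <- match.arg(which)
  protocol <- match.arg(protocol)
  if (which == "stability")
    return(plot(x$stability[[protocol]],
                main = paste("Point of stability:", protocol), ...))
  d <- x$descriptives[x$descriptives$protocol == protocol, ]
  d <- d[d$population %in% c("transdiagnostic", "MNI152", "Ernie"), ]
  bp <- graphics::barplot(d$mean, names.arg = d$population,
                          ylim = c(0, max(d$mean + ifelse(is.na(d$sd), 0, d$sd)) * 1.15),
                          ylab = "E-field magnitude (V/m)",
                          main = protocol, ...)
  ok <- !is.na(d$sd)
  graphics::arrows(bp[ok], d$mean[ok] - d$sd[ok], bp[ok],
                   d$mean[ok] + d$sd[ok], angle = 90, code = 3, length = 0.06)
  invisible(x)
}

#' Write a report to disk
#'
#' Emits a machine-readable JSON report (full precision) plus delimited
#' tables: descriptives, the twelve ANOVAs, post hocs, percent
#' differences, and one per-size stability table per protocol.
#'
#' @param report An `efield_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "efield_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  anova_row <- function(a, family, protocol)
    data.frame(family = family, protocol = protocol, f_stat = a$f_stat,
               df_between = a$df_between, df_within = a$df_within,
               p_value = a$p_value, eta_p2 = a$eta_p2,
               ss_between = a$ss_between, ss_within = a$ss_within)
  prot <- protocols()
  anovas <- do.call(rbind, c(
    lapply(prot, function(p) anova_row(report$omnibus[[p]], "omnibus", p)),
    lapply(prot, function(p) anova_row(report$diagnosis[[p]]$anova, "diagnosis", p)),
    lapply(prot, function(p) anova_row(report$sex[[p]], "sex", p))
  ))
  utils::write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(anovas, file.path(dir, "anovas.csv"), row.names = FALSE)
  posthoc <- do.call(rbind, lapply(prot, function(p) {
    ph <- as.data.frame(report$diagnosis[[p]]$posthoc)
    cbind(protocol = p, ph)
  }))
  utils::write.csv(posthoc, file.path(dir, "posthoc.csv"), row.names = FALSE)
  utils::write.csv(report$percent_diffs, file.path(dir, "percent_differences.csv"),
                   row.names = FALSE)
  for (p in prot)
    utils::write.csv(report$stability[[p]]$per_size,
                     file.path(dir, paste0("stability_", p, ".csv")),
                     row.names = FALSE)
  json <- list(
    conclusion = report$conclusion,
    omnibus = lapply(report$omnibus, function(a)
      a[c("f_stat", "df_between", "df_within", "p_value", "eta_p2")]),
    diagnosis = lapply(report$diagnosis, function(d)
      list(anova = d$anova[c("f_stat", "df_between", "df_within",
                             "p_value", "eta_p2")],
           significant_pairs = paste(d$posthoc$group_a[d$posthoc$significant],
                                     d$posthoc$group_b[d$posthoc$significant],
                                     sep = "-"))),
    sex = lapply(report$sex, function(a)
      a[c("f_stat", "df_between", "df_within", "p_value", "eta_p2")]),
    percent_diffs = report$percent_diffs,
    outlier_counts = lapply(report$outlier_audit, `[[`, "count"),
    pos = lapply(report$stability, function(s)
      list(pos = s$pos, reached = s$reached,
           corridor = as.list(s$corridor))),
    template_note = report$template_note,
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
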