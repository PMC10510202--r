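#' Stimulation protocols
#'
#' The four stimulation protocols covered by the pipeline: TMS and tES,
#' each over the motor (C3) and prefrontal (F3) cortex. TMS protocols are
#' dose-individualized via the resting motor threshold; tES protocols use a
#' fixed 2 mA current.
#'
#' @return Character vector of the four protocol names, in canonical order.
#' @export
#' @examples
#' protocols()
protocols <- function() {
  c("motor_TMS", "prefrontal_TMS", "motor_tES", "prefrontal_tES")
}

#' Diagnostic groups and default cohort sizes
#'
#' @return Named integer vector: default number of subjects per diagnostic
#'   group (healthy controls, alcohol use disorder, tobacco use disorder,
#'   generalized anxiety, depression). The defaults sum to 195.
#' @export
#' @examples
#' sum(diagnoses())
diagnoses <- function() {
  c(healthy = 31L, alcohol_use = 87L, tobacco_use = 31L,
    anxiety = 25L, depression = 21L)
}

# Reference per-(diagnosis, protocol) E-field moments in V/m.
# Rows follow diagnoses(); columns follow protocols().
.ref_means <- function() {
  m <- rbind(
    healthy     = c(84.20, 79.23, 0.343, 0.310),
    alcohol_use = c(81.60, 76.35, 0.341, 0.291),
    tobacco_use = c(90.96, 87.30, 0.376, 0.318),
    anxiety     = c(95.76, 88.75, 0.350, 0.289),
    depression  = c(81.11, 78.30, 0.327, 0.299)
  )
  colnames(m) <- protocols()
  m
}

.ref_sds <- function() {
  m <- rbind(
    healthy     = c(14.48, 13.11, 0.059, 0.052),
    alcohol_use = c(13.66, 12.43, 0.064, 0.057),
    tobacco_use = c(15.52, 17.74, 0.098, 0.087),
    anxiety     = c(15.90, 13.44, 0.082, 0.062),
    depression  = c(17.17, 17.25, 0.080, 0.070)
  )
  colnames(m) <- protocols()
  m
}

#' Template head model E-field values
#'
#' Per-protocol E-field magnitudes (V/m) for the two template head models:
#' the MNI-152 composite brain and the Ernie example head. The source
#' publications report the motor-TMS pair inconsistently between their
#' summary table (MNI-152 = 81.46, Ernie = 78.16) and their results text
#' (MNI-152 = 78.16, Ernie = 81.46); both assignments are supported and
#' the discrepancy only affects which template a motor-TMS value is
#' attributed to, never any omnibus F statistic.
#'
#' @param assignment `"results_text"` (default) or `"table"`; which reading
#'   of the motor-TMS column to use.
#' @return A 2 x 4 numeric matrix (rows `MNI152`, `Ernie`; columns
#'   [protocols()]), in V/m.
#' @export
#' @examples
#' default_templates()
default_templates <- function(assignment = c("results_text", "table")) {
  assignment <- match.arg(assignment)
  motor_tms <- if (assignment == "results_text") c(78.16, 81.46) else c(81.46, 78.16)
  m <- cbind(motor_tms, c(80.14, 72.58), c(0.293, 0.286), c(0.294, 0.244))
  dimnames(m) <- list(c("MNI152", "Ernie"), protocols())
  m
}

#' Stimulation target regions of interest
#'
#' MNI coordinates (mm, RAS) of the cortical projections of the C3 (motor)
#' and F3 (prefrontal) scalp electrode positions, used as centers of the
#' 10 mm spherical gray-matter ROIs over which E-field magnitude is
#' averaged.
#'
#' @return Named list of two [roi_spec()] objects, `motor` and `prefrontal`.
#' @export
#' @examples
#' roi_targets()$motor
roi_targets <- function() {
  list(
    motor      = roi_spec(center = c(-52.2, -16.4, 57.8), radius = 10),
    prefrontal = roi_spec(center = c(-35.5, 49.4, 32.4),  radius = 10)
  )
}

#' Reference group-summary table
#'
#' Per-(population, protocol) sufficient statistics (n, mean, SD in V/m)
#' for the reference transdiagnostic cohort: the five diagnostic groups,
#' the pooled transdiagnostic group, and the two singleton templates.
#'
#' @param protocol One of [protocols()].
#' @param populations `"diagnosis"` (five diagnostic groups),
#'   `"templates"` (transdiagnostic group plus the two templates), or
#'   `"all"`.
#' @param assignment Passed to [default_templates()].
#' @return Data frame with columns `label`, `n`, `mean`, `sd` suitable for
#'   [anova_from_summaries()].
#' @export
#' @examples
#' reference_summaries("motor_TMS", "diagnosis")
reference_summaries <- function(protocol = protocols(),
                                populations = c("diagnosis", "templates", "all"),
                                assignment = c("results_text", "table")) {
  protocol <- match.arg(protocol)
  populations <- match.arg(populations)
  n <- diagnoses()
  diag_df <- data.frame(
    label = names(n), n = unname(n),
    mean = .ref_means()[names(n), protocol],
    sd = .ref_sds()[names(n), protocol],
    row.names = NULL, stringsAsFactors = FALSE
  )
  trans <- data.frame(label = "transdiagnostic", n = 195L,
                      mean = .ref_transdiagnostic()[["mean"]][protocol],
                      sd = .ref_transdiagnostic()[["sd"]][protocol],
                      row.names = NULL, stringsAsFactors = FALSE)
  tmpl <- default_templates(match.arg(assignment))
  tmpl_df <- data.frame(label = rownames(tmpl), n = 1L,
                        mean = tmpl[, protocol], sd = 0,
                        row.names = NULL, stringsAsFactors = FALSE)
  switch(populations,
    diagnosis = diag_df,
    templates = rbind(trans, tmpl_df),
    all = rbind(diag_df, trans, tmpl_df)
  )
}

# Pooled transdiagnostic (N = 195) moments per protocol, V/m.
.ref_transdiagnostic <- function() {
  list(
    mean = c(motor_TMS = 85.26, prefrontal_TMS = 80.35,
             motor_tES = 0.347, prefrontal_tES = 0.299),
    sd   = c(motor_TMS = 15.54, prefrontal_TMS = 14.88,
             motor_tES = 0.075, prefrontal_tES = 0.064)
  )
}
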