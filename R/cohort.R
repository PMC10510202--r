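#' Cohort generation parameters
#'
#' Bundles everything the synthetic cohort generator needs: per-(diagnosis,
#' protocol) E-field moments, group and sex counts, the resting motor
#' threshold (rMT) distribution, template head-model values, and the
#' generation mode. Defaults reproduce the reference transdiagnostic
#' cohort: 195 subjects in 5 diagnostic groups (31/87/31/25/21), 106 men
#' and 89 women, rMT ~ 50.46 +/- 8.91 %MSO truncated to [31, 78], and the
#' reference per-cell E-field means and SDs.
#'
#' @param means,sds Numeric matrices (diagnosis x protocol, V/m) of target
#'   marginal E-field moments per cell. Row and column names must match
#'   `group_n` and [protocols()].
#' @param group_n Named integer vector of subjects per diagnostic group.
#' @param sex_n Named integer vector `c(male=, female=)` summing to
#'   `sum(group_n)`; if `NULL`, derived from the default 106/195 male
#'   proportion.
#' @param rmt_mean,rmt_sd,rmt_bounds rMT distribution in %MSO: mean, SD,
#'   and truncation bounds.
#' @param templates Template value matrix as from [default_templates()].
#' @param template_assignment Which motor-TMS template reading to use when
#'   `templates` is not supplied; see [default_templates()].
#' @param mode `"direct"`: each E-field is drawn from a zero-truncated
#'   normal with the cell's moments. `"mechanistic"`: TMS E-fields are
#'   `gain_i * dIdt_i` with a per-subject lognormal anatomical gain
#'   calibrated by moment matching so cell marginals still hit the targets,
#'   and tES E-fields are `gain'_i * 2 mA`, independent of rMT.
#' @param latent_loading Loading in [0, 1) of a shared per-subject
#'   anatomical latent factor inducing correlation of the four protocol
#'   fields within subject (default 0.5).
#' @param stim_multiplier Treatment dose as a multiple of rMT (default 1.2).
#' @param max_didt Maximal coil dI/dt output in A/s (default 150e6).
#' @param tes_current_mA Fixed tES current in mA (default 2).
#' @param seed Master seed; per-subject streams are derived from it by a
#'   counter offset so cohort content does not depend on generation order.
#' @return Object of class `cohort_params`.
#' @export
#' @examples
#' p <- cohort_params(seed = 1)
#' sum(p$group_n)
cohort_params <- function(means = .ref_means(), sds = .ref_sds(),
                          group_n = diagnoses(), sex_n = NULL,
                          rmt_mean = 50.46, rmt_sd = 8.91,
                          rmt_bounds = c(31, 78),
                          templates = NULL,
                          template_assignment = c("results_text", "table"),
                          mode = c("direct", "mechanistic"),
                          latent_loading = 0.5,
                          stim_multiplier = 1.2, max_didt = 150e6,
                          tes_current_mA = 2, seed = 1L) {
  mode <- match.arg(mode)
  template_assignment <- match.arg(template_assignment)
  if (is.null(templates)) templates <- default_templates(template_assignment)
  group_names <- if (!is.null(rownames(means))) rownames(means)
                 else if (!is.null(names(group_n))) names(group_n)
                 else paste0("group", seq_along(group_n))
  group_n <- stats::setNames(as.integer(group_n), group_names)
  if (length(group_n) != nrow(means))
    stop("group_n must have one count per row of `means`")
  if (any(group_n < 1L)) stop("all group counts must be >= 1")
  if (!identical(dim(means), dim(sds)))
    stop("`means` and `sds` must have identical shape")
  if (is.null(colnames(means))) colnames(means) <- protocols()
  if (is.null(colnames(sds))) colnames(sds) <- colnames(means)
  if (!all(colnames(means) == protocols()))
    stop("`means` columns must be the four protocols in canonical order")
  if (any(!is.finite(means)) || any(!is.finite(sds)) || any(sds < 0))
    stop("every (diagnosis, protocol) cell needs a finite mean and SD >= 0")
  if (is.null(sex_n)) {
    male <- as.integer(round(sum(group_n) * 106 / 195))
    sex_n <- c(male = male, female = sum(group_n) - male)
  }
  sex_n <- as.integer(sex_n); names(sex_n) <- c("male", "female")
  if (sum(sex_n) != sum(group_n))
    stop("sex counts must sum to the total number of subjects")
  if (!(rmt_bounds[1] < rmt_bounds[2]) || rmt_bounds[1] <= 0)
    stop("rmt_bounds must be an increasing positive pair")
  if (latent_loading < 0 || latent_loading >= 1)
    stop("latent_loading must be in [0, 1)")
  rownames(sds) <- rownames(means) <- group_names
  structure(list(
    means = means, sds = sds, group_n = group_n, sex_n = sex_n,
    rmt_mean = rmt_mean, rmt_sd = rmt_sd, rmt_bounds = as.numeric(rmt_bounds),
    templates = templates, mode = mode, latent_loading = latent_loading,
    stim_multiplier = stim_multiplier, max_didt = max_didt,
    tes_current_mA = tes_current_mA, seed = as.integer(seed)
  ), class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  %d subjects in %d diagnostic groups (%s)\n",
              sum(x$group_n), length(x$group_n),
              paste(x$group_n, collapse = "/")))
  cat(sprintf("  sex: %d male / %d female\n", x$sex_n["male"], x$sex_n["female"]))
  cat(sprintf("  rMT: %.2f +/- %.2f %%MSO, truncated to [%g, %g]\n",
              x$rmt_mean, x$rmt_sd, x$rmt_bounds[1], x$rmt_bounds[2]))
  cat(sprintf("  mode: %s; latent loading %.2f; seed %d\n",
              x$mode, x$latent_loading, x$seed))
  invisible(x)
}

# Derived per-subject seed: counter offset from the master seed, kept
# inside 32-bit integer range.
.subject_seed <- function(seed, i) {
  as.integer((as.double(seed) + 48271 * as.double(i)) %% 2147483647)
}

# Inverse-CDF draw from N(mean, sd) truncated to [lo, hi], u in (0,1).
.qtruncnorm <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# Mean and SD of dI/dt (A/s) over the truncated-normal rMT distribution,
# dosing with `multiplier` x rMT capped at 100 %MSO; quadrature so the
# cap case is exact.
.didt_moments <- function(params) {
  lo <- params$rmt_bounds[1]; hi <- params$rmt_bounds[2]
  z <- stats::pnorm(hi, params$rmt_mean, params$rmt_sd) -
    stats::pnorm(lo, params$rmt_mean, params$rmt_sd)
  dens <- function(r) stats::dnorm(r, params$rmt_mean, params$rmt_sd) / z
  d <- function(r) pmin(params$stim_multiplier * r, 100) / 100 * params$max_didt
  m1 <- stats::integrate(function(r) d(r) * dens(r), lo, hi)$value
  m2 <- stats::integrate(function(r) d(r)^2 * dens(r), lo, hi)$value
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# Lognormal gain parameters (meanlog, sdlog) so that gain x dose has the
# target mean/SD when dose has moments (dose_mean, dose_sd) and gain is
# independent of dose. Errors when the target SD is unattainable.
.gain_lognormal <- function(target_mean, target_sd, dose_mean, dose_sd, cell) {
  mu_g <- target_mean / dose_mean
  var_g <- (target_sd^2 - mu_g^2 * dose_sd^2) / (dose_mean^2 + dose_sd^2)
  if (var_g < 0)
    stop(sprintf(
      "cell %s: requested SD %.4g is below the dose-driven minimum; mechanistic calibration impossible",
      cell, target_sd))
  if (var_g == 0) return(c(meanlog = log(mu_g), sdlog = 0))
  sdlog2 <- log(1 + var_g / mu_g^2)
  c(meanlog = log(mu_g) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic stimulation cohort
#'
#' Draws one subject record per configured participant: diagnosis, sex,
#' rMT (%MSO, truncated normal), the derived treatment intensity and coil
#' dI/dt, and one E-field magnitude (V/m) per protocol. Within a subject
#' the four protocol fields share an anatomical latent factor (loading
#' `params$latent_loading`), while marginal (diagnosis, protocol) moments
#' match `params$means`/`params$sds`. Fully reproducible: each subject has
#' a private random stream derived from the master seed by counter offset,
#' so the cohort content is invariant to generation order.
#'
#' @param params A [cohort_params()] object.
#' @param seed Optional override of `params$seed`.
#' @return Data frame of class `efield_cohort` with columns `subject_id`,
#'   `diagnosis`, `sex`, `rmt_pct`, `stim_pct`, `didt_As`, and
#'   `efield_<protocol>` for the four protocols.
#' @export
#' @examples
#' co <- generate_cohort(cohort_params(seed = 7))
#' table(co$diagnosis)
generate_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.null(seed)) params$seed <- as.integer(seed)
  n_total <- sum(params$group_n)
  diag_vec <- rep(names(params$group_n), params$group_n)
  prot <- protocols()
  lam <- params$latent_loading
  resid <- sqrt(1 - lam^2)

  # sex: fixed marginal counts, permuted independently of diagnosis
  set.seed(params$seed)
  sex_vec <- sample(rep(c("male", "female"), params$sex_n))

  mech <- params$mode == "mechanistic"
  if (mech) {
    dm <- .didt_moments(params)
    tes_dose <- c(mean = params$tes_current_mA, sd = 0)
    gain_pars <- array(NA_real_, c(nrow(params$means), 4, 2),
                       dimnames = list(rownames(params$means), prot,
                                       c("meanlog", "sdlog")))
    for (g in rownames(params$means)) for (p in prot) {
      dose <- if (grepl("TMS", p)) dm else tes_dose
      gain_pars[g, p, ] <- .gain_lognormal(
        params$means[g, p], params$sds[g, p], dose[["mean"]], dose[["sd"]],
        paste(g, p, sep = "/"))
    }
  }

  rmt <- numeric(n_total)
  ef <- matrix(NA_real_, n_total, 4, dimnames = list(NULL, prot))
  for (i in seq_len(n_total)) {
    set.seed(.subject_seed(params$seed, i))
    u <- stats::runif(6)
    rmt[i] <- .qtruncnorm(u[1], params$rmt_mean, params$rmt_sd,
                          params$rmt_bounds[1], params$rmt_bounds[2])
    z <- stats::qnorm(u[2])
    if (mech) {
      didt_i <- rmt_to_didt(rmt[i], params$stim_multiplier, params$max_didt)
      for (k in seq_along(prot)) {
        p <- prot[k]
        gp <- gain_pars[diag_vec[i], p, ]
        gain <- exp(gp[["meanlog"]] +
                      gp[["sdlog"]] * (lam * z + resid * stats::qnorm(u[2 + k])))
        dose <- if (grepl("TMS", p)) didt_i else params$tes_current_mA
        ef[i, k] <- gain * dose
      }
    } else {
      for (k in seq_along(prot)) {
        m <- params$means[diag_vec[i], prot[k]]
        s <- params$sds[diag_vec[i], prot[k]]
        if (s == 0) { ef[i, k] <- m; next }
        mu_c <- m + s * lam * z
        sd_c <- s * resid
        ef[i, k] <- .qtruncnorm(u[2 + k], mu_c, sd_c, lo = 0)
      }
    }
  }

  out <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_total)),
    diagnosis = diag_vec, sex = sex_vec,
    rmt_pct = rmt,
    stim_pct = rmt_to_stim_pct(rmt, params$stim_multiplier),
    didt_As = rmt_to_didt(rmt, params$stim_multiplier, params$max_didt),
    stringsAsFactors = FALSE
  )
  for (k in seq_along(prot)) out[[paste0("efield_", prot[k])]] <- ef[, k]
  class(out) <- c("efield_cohort", "data.frame")
  out
}

.cohort_columns <- function() {
  c("subject_id", "diagnosis", "sex", "rmt_pct", "stim_pct", "didt_As",
    paste0("efield_", protocols()))
}

#' Write / read a cohort table
#'
#' Comma-delimited UTF-8 round trip of an [generate_cohort()] table with
#' the fixed header
#' `subject_id,diagnosis,sex,rmt_pct,stim_pct,didt_As,efield_motor_TMS,...`.
#' Numeric fields are written with 15 significant digits so the round trip
#' is faithful well past the 4-decimal printed precision of V/m values.
#'
#' @param cohort An `efield_cohort` data frame.
#' @param path File path.
#' @param valid_diagnoses Character vector of accepted diagnosis labels;
#'   rows with other labels raise an error naming the label and line.
#'   `NULL` disables the check.
#' @return `read_cohort` returns an `efield_cohort` data frame;
#'   `write_cohort` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  miss <- setdiff(.cohort_columns(), names(cohort))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  out <- cohort[, .cohort_columns(), drop = FALSE]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, valid_diagnoses = names(diagnoses())) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(.cohort_columns(), names(df))
  if (length(miss)) stop("malformed cohort file, missing columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(valid_diagnoses) && nrow(df)) {
    bad <- which(!(df$diagnosis %in% valid_diagnoses))
    if (length(bad))
      stop(sprintf("unknown diagnosis label '%s' at line %d of %s",
                   df$diagnosis[bad[1]], bad[1] + 1L, path))
  }
  num <- setdiff(.cohort_columns(), c("subject_id", "diagnosis", "sex"))
  if (nrow(df) == 0) {
    df[num] <- lapply(df[num], as.numeric)
    df[c("subject_id", "diagnosis", "sex")] <-
      lapply(df[c("subject_id", "diagnosis", "sex")], as.character)
  }
  bad_num <- which(vapply(df[num], function(v) !is.numeric(v), TRUE))
  if (length(bad_num))
    stop("malformed cohort file: non-numeric values in column ",
         num[bad_num[1]])
  df <- df[, .cohort_columns(), drop = FALSE]
  class(df) <- c("efield_cohort", "data.frame")
  df
}

#' Write / read cohort parameters as a config file
#'
#' Serializes a [cohort_params()] object to human-editable YAML (and back).
#' The file shipped at
#' `system.file("extdata", "default_cohort.yaml", package = "efieldstats")`
#' encodes the reference cohort parameterization.
#'
#' @param params A `cohort_params` object.
#' @param path File path.
#' @return `read_cohort_params` returns a `cohort_params` object.
#' @export
write_cohort_params <- function(params, path) {
  stopifnot(inherits(params, "cohort_params"))
  rows_as_list <- function(m) {
    out <- lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    names(out) <- rownames(m)
    out
  }
  x <- unclass(params)
  x$means <- rows_as_list(params$means)
  x$sds <- rows_as_list(params$sds)
  x$templates <- rows_as_list(params$templates)
  x$group_n <- as.list(params$group_n)
  x$sex_n <- as.list(params$sex_n)
  x$protocols <- protocols()
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_params
#' @export
read_cohort_params <- function(path) {
  x <- yaml::read_yaml(path)
  mk <- function(lst) {
    m <- do.call(rbind, lapply(lst, as.numeric))
    colnames(m) <- x$protocols
    m
  }
  cohort_params(
    means = mk(x$means), sds = mk(x$sds),
    group_n = unlist(x$group_n), sex_n = unlist(x$sex_n),
    rmt_mean = x$rmt_mean, rmt_sd = x$rmt_sd,
    rmt_bounds = as.numeric(x$rmt_bounds),
    templates = mk(x$templates), mode = x$mode,
    latent_loading = x$latent_loading,
    stim_multiplier = x$stim_multiplier, max_didt = x$max_didt,
    tes_current_mA = x$tes_current_mA, seed = x$seed
  )
}
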