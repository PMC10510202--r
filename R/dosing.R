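#' Stimulation intensity from resting motor threshold
#'
#' Treatment intensity is conventionally dosed relative to the resting
#' motor threshold (rMT), e.g. 120% rMT, expressed in percent of maximal
#' stimulator output (%MSO) and capped at 100%.
#'
#' @param rmt_pct rMT in %MSO, in (0, 100].
#' @param multiplier Dose multiplier (default 1.2, i.e. 120% rMT).
#' @return Stimulation intensity in %MSO, capped at 100.
#' @export
#' @examples
#' rmt_to_stim_pct(50.46)  # 60.552 %MSO
rmt_to_stim_pct <- function(rmt_pct, multiplier = 1.2) {
  if (any(!is.finite(rmt_pct)) || any(rmt_pct <= 0) || any(rmt_pct > 100))
    stop("rmt_pct must be in (0, 100]")
  if (!is.finite(multiplier) || multiplier <= 0)
    stop("multiplier must be > 0")
  pmin(multiplier * rmt_pct, 100)
}

#' Coil current rate from resting motor threshold
#'
#' Converts a motor-threshold-based stimulator setting into the coil
#' current rate dI/dt (A/s) passed to TMS field models: the %MSO at
#' `multiplier` times rMT (capped at 100%) times the machine's maximal
#' dI/dt output.
#'
#' @param rmt_pct rMT in %MSO, in (0, 100].
#' @param multiplier Dose multiplier (default 1: dI/dt at rMT itself).
#' @param max_didt Maximal stimulator-coil dI/dt output in A/s
#'   (default 150e6, a MagVenture MagPro with a Cool-B65 coil).
#' @return dI/dt in A/s.
#' @export
#' @examples
#' rmt_to_didt(50)                    # 75e6 A/s
#' rmt_to_didt(50.46, multiplier = 1.2)
rmt_to_didt <- function(rmt_pct, multiplier = 1, max_didt = 150e6) {
  if (!is.finite(max_didt) || max_didt <= 0)
    stop("max_didt must be > 0")
  rmt_to_stim_pct(rmt_pct, multiplier) / 100 * max_didt
}
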