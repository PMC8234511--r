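#' Estimated GFR by the CKD-EPI 2009 creatinine equation
#'
#' `eGFR = 141 * min(Scr/kappa, 1)^alpha * max(Scr/kappa, 1)^-1.209 *
#' 0.993^age * 1.018[female] * 1.159[Black]`, with `kappa` 0.7 (female) /
#' 0.9 (male) and `alpha` -0.329 / -0.411. The race coefficient is
#' configurable and OFF by default, matching UK laboratory practice in the
#' study era, which applied the non-Black coefficient universally.
#'
#' @param scr Serum creatinine, mg/dL (positive).
#' @param age Age in years (adults only, >= 18).
#' @param sex `"female"` or `"male"` (recycled against `scr`).
#' @param race_coefficient Multiply by 1.159 (default `FALSE`).
#' @return eGFR in mL/min/1.73 m^2; strictly decreasing in `scr` at fixed
#'   age and sex.
#' @examples
#' ckd_epi_egfr(0.9, 60, "female") # about 70
#' @export
ckd_epi_egfr <- function(scr, age, sex, race_coefficient = FALSE) {
  if (any(scr <= 0)) abort("Serum creatinine must be positive.")
  if (any(age < 18)) {
    abort("The CKD-EPI adult equation applies from age 18; pediatric equations are out of scope.")
  }
  sex <- rep_len(as.character(sex), length(scr))
  if (!all(sex %in% c("female", "male"))) {
    abort("`sex` must be \"female\" or \"male\".")
  }
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  egfr <- 141 *
    pmin(scr / kappa, 1)^alpha *
    pmax(scr / kappa, 1)^-1.209 *
    0.993^age *
    ifelse(sex == "female", 1.018, 1)
  if (race_coefficient) egfr <- egfr * 1.159
  egfr
}

#' Ascertain progression to CKD G4-G5 from longitudinal eGFR
#'
#' The outcome requires a minimum of two *outpatient* eGFR assessments below
#' 30 mL/min/1.73 m^2, separated by at least 3 months (operationalized as
#' >= 90 days), inside the follow-up window. Cohort entry is 90 days after
#' discharge and the horizon is 1 year; windows are half-open at the start
#' and closed at the end, `(index_day, index_day + horizon_days]`. Absent or
#' insufficient data yields `FALSE` (no outcome observed), never an error.
#'
#' @param data eGFR assessments for one subject: `day` (days since
#'   discharge), `egfr`, `setting` (`"inpatient"`/`"outpatient"`).
#' @param index_day Cohort entry, days after discharge (default 90).
#' @param horizon_days Follow-up horizon after entry (default 365).
#' @param egfr_threshold Qualifying eGFR bound (default 30).
#' @param min_separation_days Minimum spacing of the two qualifying
#'   assessments (default 90, the ">= 3 months" rule).
#' @return Single logical.
#' @export
ascertain_ckd_g45 <- function(data, index_day = 90, horizon_days = 365,
                              egfr_threshold = 30,
                              min_separation_days = 90) {
  if (is.null(data) || nrow(data) == 0L) return(FALSE)
  stopifnot(all(c("day", "egfr", "setting") %in% names(data)))
  q <- data[data$setting == "outpatient" &
              data$egfr < egfr_threshold &
              data$day > index_day &
              data$day <= index_day + horizon_days, ]
  if (nrow(q) < 2L) return(FALSE)
  (max(q$day) - min(q$day)) >= min_separation_days
}

#' Ascertain death or unplanned readmission within the post-discharge window
#'
#' `TRUE` iff a `death` or `readmission` event occurs in
#' `(0, window_days]` days after discharge (half-open at discharge, closed
#' at the horizon, so an event on day 91 is outside a 90-day window).
#'
#' @param events Event slice for one case: `activity`, `day` (days since
#'   discharge; the discharge event itself, at day 0, may be present).
#' @param window_days Horizon (default 90).
#' @return Single logical. Events timestamped before discharge signal a
#'   malformed log and raise an error.
#' @export
ascertain_death_or_readmission <- function(events, window_days = 90) {
  if (is.null(events) || nrow(events) == 0L) return(FALSE)
  stopifnot(all(c("activity", "day") %in% names(events)))
  if (any(events$day < 0)) {
    abort("Malformed event log: events timestamped before discharge.")
  }
  any(events$activity %in% c("death", "readmission") &
        events$day > 0 & events$day <= window_days)
}
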