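#' KDIGO-style staging multipliers
#'
#' The severity staging convention applied once an AKI criterion has fired:
#' stage 1 by default, stage 2 when the index creatinine reaches
#' `stage2_mult` times the reference value of the firing criterion, stage 3
#' when it reaches `stage3_mult` times the reference or an absolute level of
#' `stage3_abs` mg/dL. The defaults follow the usual KDIGO convention
#' (2.0x, 3.0x, 4.0 mg/dL) and are configurable because published
#' KDIGO-based algorithms differ in detail.
#'
#' @param stage2_mult,stage3_mult Ratio thresholds (index / reference).
#' @param stage3_abs Absolute index creatinine (mg/dL) implying stage 3.
#' @return A named list used by the AKI detectors.
#' @export
kdigo_multipliers <- function(stage2_mult = 2.0, stage3_mult = 3.0,
                              stage3_abs = 4.0) {
  stopifnot(stage2_mult > 1, stage3_mult >= stage2_mult, stage3_abs > 0)
  list(stage2_mult = stage2_mult, stage3_mult = stage3_mult,
       stage3_abs = stage3_abs)
}

stage_from <- function(index, reference, multipliers) {
  if (index >= multipliers$stage3_mult * reference ||
      index >= multipliers$stage3_abs) return(3L)
  if (index >= multipliers$stage2_mult * reference) return(2L)
  1L
}

aki_result <- function(flag, stage, criterion, index_day = NA_real_,
                       index_scr = NA_real_, reference_scr = NA_real_) {
  tibble::tibble(flag = flag, stage = stage, criterion = criterion,
                 index_day = index_day, index_scr = index_scr,
                 reference_scr = reference_scr)
}

check_series <- function(obs) {
  if (is.null(obs) || nrow(obs) == 0L) {
    abort("Insufficient data: the creatinine series is empty.")
  }
  if (!all(c("day", "scr") %in% names(obs))) {
    abort("A creatinine series needs `day` and `scr` columns.")
  }
  obs$day <- as.numeric(obs$day)
  if (any(obs$scr <= 0)) abort("Serum creatinine must be positive.")
  dplyr::arrange(obs, .data$day)
}

#' Detect and stage AKI from serial creatinine (Grampian algorithm)
#'
#' Applies the KDIGO-based flagging rules used to define AKI for the Aberdeen
#' readmissions model. Every in-admission creatinine is tested as an index
#' value against three criteria evaluated on earlier observations:
#'
#' 1. `delta48h` — a rise of more than 0.3 mg/dL above the lowest creatinine
#'    in the preceding 48 hours;
#' 2. `ratio7d` — a 50 percent rise (index >= 1.5x) over the lowest
#'    creatinine in the past 7 days;
#' 3. `ratio8_90d` — a 50 percent rise over the *median* creatinine 8-90 days
#'    back, falling back to the 91-365 day median (`ratio91_365d`) only when
#'    no sample exists in the closer window; with no samples in either
#'    window the criterion is skipped (not an error).
#'
#' AKI is flagged if any criterion fires on any index value. The stage is
#' assigned by [kdigo_multipliers()] relative to the reference value of the
#' firing criterion; when several criteria fire, the one yielding the highest
#' stage is reported, ties broken in the order listed above.
#'
#' Lookback windows are taken relative to each index time `t` (in days):
#' `[t-2, t)`, `[t-7, t)`, `[t-90, t-8]`, `[t-365, t-91]`.
#'
#' @param obs Data frame for one subject: `day` (numeric days on any common
#'   origin, or dates), `scr` (serum creatinine, mg/dL). Pre-admission
#'   observations supply the lookback baselines.
#' @param admission Length-2 numeric: first and last day of the admission;
#'   only observations inside it are tested as index values. Defaults to the
#'   span of the series.
#' @param multipliers Staging convention, see [kdigo_multipliers()].
#' @return One-row tibble: `flag`, `stage` (0-3), `criterion` (one of
#'   `delta48h`, `ratio7d`, `ratio8_90d`, `ratio91_365d`, `none`),
#'   `index_day`, `index_scr`, `reference_scr`.
#' @examples
#' obs <- tibble::tibble(day = c(-1, 0), scr = c(1.0, 1.35))
#' detect_aki_grampian(obs, admission = c(0, 3)) # delta48h, stage 1
#' @export
detect_aki_grampian <- function(obs, admission = NULL,
                                multipliers = kdigo_multipliers()) {
  obs <- check_series(obs)
  if (is.null(admission)) admission <- range(obs$day)
  admission <- as.numeric(admission)
  idx <- which(obs$day >= admission[1] & obs$day <= admission[2])
  if (!length(idx)) {
    abort("Insufficient data: no creatinine observed during the admission.")
  }
  crit_order <- c("delta48h", "ratio7d", "ratio8_90d", "ratio91_365d")
  best <- NULL
  for (i in idx) {
    t <- obs$day[i]
    c_i <- obs$scr[i]
    prior <- obs[obs$day < t, ]
    fired <- list()
    w48 <- prior$scr[prior$day >= t - 2]
    if (length(w48) && c_i - min(w48) > 0.3) {
      fired$delta48h <- min(w48)
    }
    w7 <- prior$scr[prior$day >= t - 7]
    if (length(w7) && c_i >= 1.5 * min(w7)) {
      fired$ratio7d <- min(w7)
    }
    w890 <- prior$scr[prior$day >= t - 90 & prior$day <= t - 8]
    if (length(w890)) {
      if (c_i >= 1.5 * median(w890)) fired$ratio8_90d <- median(w890)
    } else {
      w91365 <- prior$scr[prior$day >= t - 365 & prior$day <= t - 91]
      if (length(w91365) && c_i >= 1.5 * median(w91365)) {
        fired$ratio91_365d <- median(w91365)
      }
    }
    for (crit in intersect(crit_order, names(fired))) {
      st <- stage_from(c_i, fired[[crit]], multipliers)
      cand <- list(stage = st, criterion = crit, day = t, scr = c_i,
                   ref = fired[[crit]])
      if (is.null(best) || st > best$stage) best <- cand
    }
  }
  if (is.null(best)) {
    return(aki_result(FALSE, 0L, "none"))
  }
  aki_result(TRUE, best$stage, best$criterion, best$day, best$scr, best$ref)
}

#' Detect and stage AKI from serial creatinine (Alberta algorithm)
#'
#' AKI is established from a rise in creatinine during hospitalization of
#' more than 0.3 mg/dL or more than 50 percent over the most recent
#' *outpatient* pre-hospital baseline taken 7-365 days before admission.
#' With no qualifying baseline the result is explicitly indeterminate
#' (`flag = NA`), which is distinct from "no AKI".
#'
#' @inheritParams detect_aki_grampian
#' @param obs As in [detect_aki_grampian()] plus a `setting` column
#'   (`"inpatient"`/`"outpatient"`) used to find the outpatient baseline.
#' @param admission Length-2 numeric, first and last day of the admission
#'   (required: the baseline window is anchored at its start).
#' @return One-row tibble as in [detect_aki_grampian()], with `criterion`
#'   `alberta_baseline`, `none`, or `indeterminate` (flag `NA`).
#' @export
detect_aki_alberta <- function(obs, admission,
                               multipliers = kdigo_multipliers()) {
  obs <- check_series(obs)
  if (!"setting" %in% names(obs)) {
    abort("The Alberta algorithm needs a `setting` column (inpatient/outpatient).")
  }
  admission <- as.numeric(admission)
  base_win <- obs[obs$setting == "outpatient" &
                    obs$day >= admission[1] - 365 &
                    obs$day <= admission[1] - 7, ]
  if (nrow(base_win) == 0L) {
    return(aki_result(NA, NA_integer_, "indeterminate"))
  }
  baseline <- base_win$scr[which.max(base_win$day)]
  inhosp <- obs[obs$day >= admission[1] & obs$day <= admission[2], ]
  if (nrow(inhosp) == 0L) {
    abort("Insufficient data: no creatinine observed during the admission.")
  }
  peak <- max(inhosp$scr)
  peak_day <- inhosp$day[which.max(inhosp$scr)]
  if (peak - baseline > 0.3 || peak > 1.5 * baseline) {
    aki_result(TRUE, stage_from(peak, baseline, multipliers),
               "alberta_baseline", peak_day, peak, baseline)
  } else {
    aki_result(FALSE, 0L, "none", peak_day, peak, baseline)
  }
}

#' Detect AKI for every subject in a longitudinal creatinine table
#'
#' Data-frame-first wrapper over [detect_aki_grampian()] /
#' [detect_aki_alberta()]: groups a long table of creatinine observations by
#' subject and returns one detection row per subject.
#'
#' @param data Long table: `subject_id`, `day`, `scr`, and (for the Alberta
#'   algorithm) `setting`.
#' @param admissions Table `subject_id`, `admission_day`, `discharge_day`;
#'   when `NULL` each subject's full span is treated as the admission
#'   (Grampian algorithm only).
#' @param method `"grampian"` or `"alberta"`.
#' @param multipliers See [kdigo_multipliers()].
#' @return Tibble, one row per subject: `subject_id` plus the detection
#'   columns of the single-series functions.
#' @export
detect_aki <- function(data, admissions = NULL,
                       method = c("grampian", "alberta"),
                       multipliers = kdigo_multipliers()) {
  method <- match.arg(method)
  if (method == "alberta" && is.null(admissions)) {
    abort("The Alberta algorithm needs an `admissions` table.")
  }
  data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(obs, key) {
      adm <- NULL
      if (!is.null(admissions)) {
        row <- admissions[admissions$subject_id == key$subject_id, ]
        if (nrow(row) != 1L) {
          abort(paste0("No admission metadata for subject `",
                       key$subject_id, "`."))
        }
        adm <- c(row$admission_day, row$discharge_day)
      }
      if (method == "grampian") {
        detect_aki_grampian(obs, admission = adm, multipliers = multipliers)
      } else {
        detect_aki_alberta(obs, admission = adm, multipliers = multipliers)
      }
    }) |>
    dplyr::ungroup()
}
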