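## Independent oracles and tiny fixture builders used across the suite.

# Exhaustive-pair concordance: mean over all event x non-event pairs of
# 1 (concordant), 1/2 (tied), 0 (discordant).
c_stat_brute <- function(risk, y) {
  ev <- risk[y == 1]
  ne <- risk[y == 0]
  tot <- 0
  for (a in ev) for (b in ne) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ev) * length(ne))
}

# Brute-force KDIGO evaluator: enumerates all three criteria independently
# on every in-admission observation window, then applies the same staging
# and tie-break conventions (highest stage, listed criterion order,
# earliest index).
aki_brute <- function(obs, admission, multipliers = kdigo_multipliers()) {
  obs <- obs[order(obs$day), ]
  stage_of <- function(c_i, ref) {
    if (c_i >= multipliers$stage3_mult * ref ||
        c_i >= multipliers$stage3_abs) 3L
    else if (c_i >= multipliers$stage2_mult * ref) 2L
    else 1L
  }
  crit_order <- c("delta48h", "ratio7d", "ratio8_90d", "ratio91_365d")
  cands <- list()
  for (i in seq_len(nrow(obs))) {
    t <- obs$day[i]; c_i <- obs$scr[i]
    if (t < admission[1] || t > admission[2]) next
    before <- obs[obs$day < t, ]
    refs <- list()
    w <- before$scr[before$day >= t - 2]
    if (length(w) && c_i - min(w) > 0.3) refs$delta48h <- min(w)
    w <- before$scr[before$day >= t - 7]
    if (length(w) && c_i >= 1.5 * min(w)) refs$ratio7d <- min(w)
    w <- before$scr[before$day >= t - 90 & before$day <= t - 8]
    if (length(w)) {
      if (c_i >= 1.5 * median(w)) refs$ratio8_90d <- median(w)
    } else {
      w <- before$scr[before$day >= t - 365 & before$day <= t - 91]
      if (length(w) && c_i >= 1.5 * median(w)) refs$ratio91_365d <- median(w)
    }
    for (cr in crit_order) {
      if (!is.null(refs[[cr]])) {
        cands[[length(cands) + 1]] <-
          list(criterion = cr, stage = stage_of(c_i, refs[[cr]]))
      }
    }
  }
  if (!length(cands)) {
    return(list(flag = FALSE, stage = 0L, criterion = "none"))
  }
  stages <- vapply(cands, `[[`, integer(1), "stage")
  best <- cands[[which.max(stages)]] # first max: evaluation order tie-break
  list(flag = TRUE, stage = best$stage, criterion = best$criterion)
}

# A subject at the reference level of every aberdeen-model term.
aberdeen_reference_subject <- function(n = 1) {
  tibble::tibble(
    age = rep(0, n), residential_care = 0, rural = 0, prior_admissions = 0,
    emergency_admission = 0, aki_stage = "0", baseline_egfr = 0,
    cancer = 0, cardiac_failure = 0, diabetes = 0, pulmonary = 0
  )
}

# Small random cohort with risks and outcomes (no model involved).
random_risk_cohort <- function(n, tie_prob = 0.2) {
  risk <- runif(n)
  ties <- runif(n) < tie_prob
  risk[ties] <- sample(c(0.2, 0.5, 0.8), sum(ties), replace = TRUE)
  y <- rbinom(n, 1, 0.5)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  tibble::tibble(risk = risk, y = y)
}

# Two-case toy event log: one monitored readmission (GP at day 5,
# readmission day 9) and one straight-to-readmission case (day 13).
toy_event_log <- function() {
  tibble::tibble(
    case_id = c("a", "a", "a", "b", "b"),
    activity = c("discharge", "gp_monitoring", "readmission",
                 "discharge", "readmission"),
    day = c(0, 5, 9, 0, 13)
  )
}
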