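## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Cohort simulation configurations
#'
#' A cohort configuration bundles the marginal covariate distributions, the
#' outcome-generating ("true") model, a target outcome prevalence and an
#' optional miscalibration `(intercept_shift, slope_factor)` applied on the
#' log-odds scale. Covariates are drawn independently from their marginals -
#' a documented simplification: only marginal summaries of the study
#' settings are public, so no joint structure is claimed.
#'
#' Two ready-made scenarios are provided, parameterized from the published
#' validation-cohort characteristic tables:
#'
#' * `grampian_cohort_config()` — all-hospital-survivor scenario (default
#'   n = 26,575; age 60.9 +/- 19.8; AKI stages 8.7/2.3/1.5 percent; outcome
#'   prevalence 2,927/26,575 ~ 0.110). Outcomes are generated from the
#'   packaged `synthetic_grampian_truth` model (see its notes).
#' * `alberta_cohort_config()` — AKI-survivor CKD progression scenario
#'   (default n = 9,382; age 67.2 +/- 15.4; AKI stages 78.5/13.2/8.3
#'   percent; prevalence 140/9,382 ~ 0.015). Outcomes are generated from
#'   the as-printed `alberta_original` model, whose coefficients yield
#'   realistic absolute risks.
#'
#' When `target_prevalence` is set, [simulate_cohort()] solves the additive
#' intercept shift so the expected simulated prevalence matches it.
#'
#' @param n Cohort size.
#' @param covariates Named list of marginal samplers; each element is a list
#'   with `type` (`"normal"`, `"bernoulli"`, `"categorical"`,
#'   `"categorical_numeric"`) and its parameters (`mean`/`sd`/`lower`/
#'   `upper`, `p`, or `levels`/`values` + `probs`).
#' @param true_model [model_spec()] generating the outcomes.
#' @param target_prevalence Expected outcome prevalence to calibrate the
#'   intercept shift to, or `NULL` to use the model as-is.
#' @param slope_factor,intercept_shift Miscalibration of the generating law:
#'   outcome probability is `plogis(intercept_shift + slope_factor * PI)`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n, covariates, true_model,
                          target_prevalence = NULL,
                          intercept_shift = 0, slope_factor = 1) {
  stopifnot(n >= 1, inherits(true_model, "model_spec"))
  if (slope_factor <= 0) abort("`slope_factor` must be positive.")
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (cv$type == "bernoulli" && (cv$p < 0 || cv$p > 1)) {
      abort(paste0("Prevalence for `", nm, "` must lie in [0, 1]."))
    }
    if (cv$type %in% c("categorical", "categorical_numeric")) {
      if (any(cv$probs < 0) || abs(sum(cv$probs) - 1) > 1e-8) {
        abort(paste0("Category probabilities for `", nm, "` must be ",
                     "nonnegative and sum to 1."))
      }
    }
    if (cv$type == "normal" && cv$sd <= 0) {
      abort(paste0("Standard deviation for `", nm, "` must be positive."))
    }
  }
  structure(list(n = n, covariates = covariates, true_model = true_model,
                 target_prevalence = target_prevalence,
                 intercept_shift = intercept_shift,
                 slope_factor = slope_factor),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
grampian_cohort_config <- function(n = 26575) {
  cohort_config(
    n = n,
    covariates = list(
      age = list(type = "normal", mean = 60.9, sd = 19.8,
                 lower = 18, upper = 105),
      residential_care = list(type = "bernoulli", p = 0.016),
      rural = list(type = "bernoulli", p = 0.288),
      prior_admissions = list(type = "categorical_numeric", values = 0:3,
                              probs = c(0.523, 0.240, 0.115, 0.122)),
      emergency_admission = list(type = "bernoulli", p = 0.713),
      aki_stage = list(type = "categorical",
                       levels = c("0", "1", "2", "3"),
                       probs = c(0.875, 0.0865, 0.023, 0.0155)),
      baseline_egfr = list(type = "normal", mean = 86.3, sd = 26.4,
                           lower = 10, upper = 180),
      discharge_egfr = list(type = "normal", mean = 85, sd = 26,
                            lower = 5, upper = 180),
      cancer = list(type = "bernoulli", p = 0.140),
      cardiac_failure = list(type = "bernoulli", p = 0.081),
      diabetes = list(type = "bernoulli", p = 0.130),
      pulmonary = list(type = "bernoulli", p = 0.188)
    ),
    true_model = load_model("synthetic_grampian_truth"),
    target_prevalence = 2927 / 26575
  )
}

#' @rdname cohort_config
#' @export
alberta_cohort_config <- function(n = 9382) {
  cohort_config(
    n = n,
    covariates = list(
      age = list(type = "normal", mean = 67.2, sd = 15.4,
                 lower = 18, upper = 105),
      female = list(type = "bernoulli", p = 0.458),
      aki_stage = list(type = "categorical",
                       levels = c("1", "2", "3"),
                       probs = c(0.785, 0.132, 0.083)),
      baseline_scr = list(type = "normal", mean = 0.9, sd = 0.3,
                          lower = 0.3, upper = 3),
      discharge_scr_cat = list(
        type = "categorical",
        levels = c("<1.0", "1.0-<1.3", "1.3-<1.6", "1.6-<1.9", ">1.9"),
        probs = c(0.478, 0.283, 0.153, 0.050, 0.036)
      ),
      albuminuria = list(type = "categorical",
                         levels = c("normal", "mild", "heavy", "unmeasured"),
                         probs = c(0.119, 0.064, 0.034, 0.783)),
      discharge_egfr = list(type = "normal", mean = 69.1, sd = 25,
                            lower = 5, upper = 180)
    ),
    true_model = load_model("alberta_original"),
    target_prevalence = 140 / 9382
  )
}

draw_covariate <- function(cv, n) {
  switch(cv$type,
    normal = pmin(pmax(rnorm(n, cv$mean, cv$sd),
                       cv$lower %||% -Inf), cv$upper %||% Inf),
    bernoulli = rbinom(n, 1, cv$p),
    categorical = sample(cv$levels, n, replace = TRUE, prob = cv$probs),
    categorical_numeric = sample(cv$values, n, replace = TRUE,
                                 prob = cv$probs),
    abort(paste0("Unknown covariate sampler type `", cv$type, "`."))
  )
}

solve_shift <- function(pi, slope_factor, target) {
  uniroot(function(s) mean(plogis(s + slope_factor * pi)) - target,
          interval = c(-50, 50), tol = 1e-10)$root
}

#' Simulate a cohort table
#'
#' Draws covariates independently from the configured marginals, computes
#' each subject's prognostic index under the configured true model, and
#' draws the binary outcome with probability
#' `plogis(intercept_shift + slope_factor * PI)`. When the configuration
#' carries a `target_prevalence`, the intercept shift is first solved (given
#' the drawn covariates) so the expected prevalence matches it. Fully
#' deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, the covariates, `.true_risk` (the
#'   generating probability) and the outcome column named as in the true
#'   model. The solved/used intercept shift is attached as attribute
#'   `"intercept_shift"`.
#' @export
simulate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    cov <- purrr::map(config$covariates, draw_covariate, n = config$n)
    data <- tibble::as_tibble(cov)
    data <- dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%06d", seq_len(config$n))), data)
    pi <- linear_predictor(data, config$true_model)
    shift <- config$intercept_shift
    if (!is.null(config$target_prevalence)) {
      shift <- solve_shift(pi, config$slope_factor, config$target_prevalence)
    }
    p <- plogis(shift + config$slope_factor * pi)
    data$.true_risk <- p
    data[[config$true_model$outcome]] <- rbinom(config$n, 1, p)
    attr(data, "intercept_shift") <- shift
    data
  })
}

#' Redraw outcomes under a shifted and rescaled logistic law
#'
#' Emulates derivation-to-validation drift: the cohort's covariates are kept
#' and its outcomes are redrawn with probability
#' `plogis(shift + slope_factor * PI)`, where PI is the prognostic index of
#' `model` on the cohort. Instead of a shift, a target predicted-to-observed
#' ratio may be given; the shift is then solved so that the model's mean
#' predicted risk is `target_po` times the expected simulated prevalence.
#'
#' @param data Cohort table scored against `model`'s predictors.
#' @param model The scoring [model_spec()] whose miscalibration is being
#'   emulated.
#' @param shift Additive intercept shift on the log-odds scale (ignored when
#'   `target_po` is given).
#' @param slope_factor Multiplicative slope distortion (> 0); the
#'   calibration slope recovered on the redrawn outcomes converges to
#'   `slope_factor` at large n.
#' @param seed Integer seed.
#' @param target_po Optional target predicted-to-observed ratio.
#' @return `data` with the model's outcome column redrawn, `.true_risk`
#'   updated, and the shift used attached as attribute `"intercept_shift"`.
#' @export
simulate_external_shift <- function(data, model, shift = 0, slope_factor = 1,
                                    seed = 1, target_po = NULL) {
  if (slope_factor <= 0) abort("`slope_factor` must be positive.")
  pi <- linear_predictor(data, model)
  if (!is.null(target_po)) {
    stopifnot(target_po > 0)
    target_prev <- mean(plogis(pi)) / target_po
    if (target_prev >= 1) {
      abort("Target predicted-to-observed ratio implies a prevalence >= 1.")
    }
    shift <- solve_shift(pi, slope_factor, target_prev)
  }
  with_seed(seed, {
    p <- plogis(shift + slope_factor * pi)
    out <- tibble::as_tibble(data)
    out$.true_risk <- p
    out[[model$outcome]] <- rbinom(nrow(out), 1, p)
    attr(out, "intercept_shift") <- shift
    out
  })
}

## Series recipes: each constructs observations for which exactly the
## intended criterion fires at the intended stage under the Grampian rules.
## The index creatinine sits at day 1 inside an admission spanning days 0-4.
series_recipe <- function(criterion, stage) {
  b <- switch(criterion,
              delta48h = runif(1, 0.8, 1.3),
              runif(1, 0.7, 1.1))
  m <- switch(as.character(stage),
              "1" = runif(1, 1.55, 1.95),
              "2" = runif(1, 2.05, 2.95),
              "3" = runif(1, 3.05, 3.50))
  obs <- switch(criterion,
    none = {
      jit <- runif(3, -0.06, 0.06)
      tibble::tibble(day = c(-30, 1, 3), scr = b * (1 + jit),
                     setting = c("outpatient", "inpatient", "inpatient"))
    },
    delta48h = {
      u <- runif(1, 0.32, min(0.48 * b, 0.45))
      tibble::tibble(day = c(-45, 0, 1), scr = c(b, b, b + u),
                     setting = c("outpatient", "inpatient", "inpatient"))
    },
    ratio7d = tibble::tibble(day = c(-4, 1), scr = c(b, m * b),
                             setting = c("outpatient", "inpatient")),
    ratio8_90d = tibble::tibble(day = c(-30, 1), scr = c(b, m * b),
                                setting = c("outpatient", "inpatient")),
    ratio91_365d = tibble::tibble(day = c(-120, 1), scr = c(b, m * b),
                                  setting = c("outpatient", "inpatient"))
  )
  obs
}

#' Simulate serial-creatinine series with known AKI ground truth
#'
#' Generates per-subject creatinine series labelled with the rule used to
#' construct them, so AKI detection can be checked end to end: series
#' labelled with a criterion and stage are built to fire exactly that
#' criterion of [detect_aki_grampian()] at exactly that stage, and negative
#' series to fire none. Admissions span days 0-4 with the index creatinine
#' on day 1; pre-admission baselines are outpatient samples at
#' criterion-specific lookback days.
#'
#' Because a creatinine that doubles also rises by 50 percent, the 48-hour
#' absolute-delta rule can only be the *highest-stage* firing criterion at
#' stage 1; requesting delta-labelled cases is therefore only feasible
#' together with stage 1, and stages 2-3 are allocated among the ratio
#' criteria.
#'
#' @param n_subjects Number of series.
#' @param seed Integer seed.
#' @param aki_fraction Fraction of series with AKI (0-1).
#' @param stage_mix Probabilities of stages 1-3 among AKI series.
#' @param criterion_mix Probabilities over criteria `delta48h`, `ratio7d`,
#'   `ratio8_90d`, `ratio91_365d` for stage-1 series (stages 2-3 use the
#'   ratio criteria, renormalized).
#' @return Tibble: `subject_id`, `truth_flag`, `truth_stage`,
#'   `truth_criterion`, `admission_day`, `discharge_day` and `observations`
#'   (list-column of `day`/`scr`/`setting` tibbles). Unnest to get the long
#'   table consumed by [detect_aki()].
#' @export
simulate_creatinine_series <- function(n_subjects, seed, aki_fraction = 0.3,
                                       stage_mix = c(0.6, 0.25, 0.15),
                                       criterion_mix = c(delta48h = 0.25,
                                                         ratio7d = 0.35,
                                                         ratio8_90d = 0.25,
                                                         ratio91_365d = 0.15)) {
  if (aki_fraction < 0 || aki_fraction > 1) {
    abort("`aki_fraction` must lie in [0, 1].")
  }
  if (any(stage_mix < 0) || abs(sum(stage_mix) - 1) > 1e-8) {
    abort("`stage_mix` must be 3 nonnegative probabilities summing to 1.")
  }
  if (any(criterion_mix < 0) || abs(sum(criterion_mix) - 1) > 1e-8) {
    abort("`criterion_mix` must be nonnegative probabilities summing to 1.")
  }
  ratio_mix <- criterion_mix[setdiff(names(criterion_mix), "delta48h")]
  if (sum(stage_mix[2:3]) > 0 && sum(ratio_mix) <= 0) {
    abort("Infeasible mix: stages 2-3 require ratio criteria, but `criterion_mix` puts all mass on delta48h.")
  }
  with_seed(seed, {
    flag <- rbinom(n_subjects, 1, aki_fraction) == 1
    stage <- ifelse(flag, sample(1:3, n_subjects, replace = TRUE,
                                 prob = stage_mix), 0L)
    criterion <- rep("none", n_subjects)
    s1 <- which(stage == 1)
    criterion[s1] <- sample(names(criterion_mix), length(s1), replace = TRUE,
                            prob = criterion_mix)
    s23 <- which(stage >= 2)
    criterion[s23] <- sample(names(ratio_mix), length(s23), replace = TRUE,
                             prob = ratio_mix / sum(ratio_mix))
    obs <- purrr::map2(criterion, stage, series_recipe)
    tibble::tibble(
      subject_id = sprintf("P%05d", seq_len(n_subjects)),
      truth_flag = flag,
      truth_stage = as.integer(stage),
      truth_criterion = criterion,
      admission_day = 0, discharge_day = 4,
      observations = obs
    )
  })
}

#' Care-pathway simulation parameters
#'
#' @param monitoring_prob Probability that a poor-outcome case has at least
#'   one recorded care contact before its terminal event; the expected
#'   unmonitored fraction among poor outcomes is `1 - monitoring_prob`. The
#'   default 0.61 reproduces the reported 39 percent unmonitored rate.
#' @param horizon Follow-up horizon in days (default 90).
#' @param median_days_to_outcome Median of the (truncated-exponential) time
#'   from discharge to death/readmission (default 13 days).
#' @param death_fraction Fraction of poor outcomes that are deaths rather
#'   than readmissions.
#' @param contacts_mean Poisson mean for the number of monitoring contacts
#'   (plus one guaranteed contact for monitored poor-outcome cases).
#' @param activity_probs Mix of contact types (GP, outpatient clinic, A&E);
#'   the GP-dominated default mirrors monitoring being mostly primary care.
#' @param outcome_col Name of the binary poor-outcome column in the cohort.
#' @return A named list of class `pathway_params`.
#' @export
pathway_params <- function(monitoring_prob = 0.61, horizon = 90,
                           median_days_to_outcome = 13,
                           death_fraction = 0.25, contacts_mean = 1.2,
                           activity_probs = c(gp_monitoring = 0.70,
                                              outpatient_clinic = 0.15,
                                              accident_emergency = 0.15),
                           outcome_col = "death_or_readmission_90d") {
  stopifnot(monitoring_prob >= 0, monitoring_prob <= 1, horizon > 0,
            median_days_to_outcome > 0, median_days_to_outcome < horizon,
            death_fraction >= 0, death_fraction <= 1,
            all(activity_probs >= 0), abs(sum(activity_probs) - 1) < 1e-8)
  structure(list(monitoring_prob = monitoring_prob, horizon = horizon,
                 median_days_to_outcome = median_days_to_outcome,
                 death_fraction = death_fraction,
                 contacts_mean = contacts_mean,
                 activity_probs = activity_probs,
                 outcome_col = outcome_col),
            class = "pathway_params")
}

#' Simulate a post-discharge care-pathway event log
#'
#' Builds an event log satisfying the log invariants (one discharge per case
#' at day 0, time-ordered events, one terminal event last): poor-outcome
#' cases end in a death/readmission at a time drawn from an exponential
#' truncated to the horizon (median set by
#' `params$median_days_to_outcome`), preceded by monitoring contacts with
#' probability `params$monitoring_prob`; all other cases receive a Poisson
#' number of contacts and exit at `end_follow_up` on the horizon boundary.
#'
#' @param data Cohort table carrying the binary outcome column named in
#'   `params$outcome_col` (e.g. from [simulate_cohort()]).
#' @param params A [pathway_params()].
#' @param seed Integer seed.
#' @return A validated event log tibble (`case_id`, `activity`, `day`).
#' @export
simulate_care_pathways <- function(data, params = pathway_params(), seed = 1) {
  stopifnot(inherits(params, "pathway_params"))
  if (!params$outcome_col %in% names(data)) {
    abort(paste0("Cohort is missing outcome column `", params$outcome_col,
                 "`."))
  }
  y <- check_binary_outcome(data[[params$outcome_col]], require_both = FALSE)
  ids <- if ("subject_id" %in% names(data)) as.character(data$subject_id)
         else sprintf("C%06d", seq_along(y))
  rate <- log(2) / params$median_days_to_outcome
  with_seed(seed, {
    logs <- purrr::map(seq_along(y), function(i) {
      events <- tibble::tibble(case_id = ids[i], activity = "discharge",
                               day = 0)
      if (y[i] == 1) {
        u <- runif(1)
        t_event <- stats::qexp(u * stats::pexp(params$horizon, rate), rate)
        t_event <- max(t_event, 0.5)
        monitored <- runif(1) < params$monitoring_prob
        if (monitored) {
          k <- 1 + rpois(1, params$contacts_mean)
          times <- sort(runif(k, 0.02 * t_event, 0.95 * t_event))
          acts <- sample(names(params$activity_probs), k, replace = TRUE,
                         prob = params$activity_probs)
          events <- dplyr::bind_rows(events,
            tibble::tibble(case_id = ids[i], activity = acts, day = times))
        }
        terminal <- if (runif(1) < params$death_fraction) "death"
                    else "readmission"
        events <- dplyr::bind_rows(events,
          tibble::tibble(case_id = ids[i], activity = terminal,
                         day = t_event))
      } else {
        k <- rpois(1, params$contacts_mean)
        if (k > 0) {
          times <- sort(runif(k, 0.5, params$horizon - 0.5))
          acts <- sample(names(params$activity_probs), k, replace = TRUE,
                         prob = params$activity_probs)
          events <- dplyr::bind_rows(events,
            tibble::tibble(case_id = ids[i], activity = acts, day = times))
        }
        events <- dplyr::bind_rows(events,
          tibble::tibble(case_id = ids[i], activity = "end_follow_up",
                         day = params$horizon))
      }
      events
    })
    validate_event_log(dplyr::bind_rows(logs))
  })
}
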