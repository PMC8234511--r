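check_binary_outcome <- function(outcome, require_both = TRUE,
                                 what = "outcome") {
  y <- as.numeric(outcome)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    abort(paste0("`", what, "` must be binary (0/1 or logical) without missing values."))
  }
  if (require_both && length(unique(y)) < 2L) {
    abort(paste0("`", what, "` must contain both classes."))
  }
  as.integer(y)
}

clip_risk <- function(risk, eps = 1e-12) pmin(pmax(risk, eps), 1 - eps)

#' C statistic (concordance probability)
#'
#' The probability that a randomly chosen event case carries a higher
#' predicted risk than a randomly chosen non-event case, with tied risks
#' counting one half. Computed via midranks, which is exactly the exhaustive
#' pairwise count. The optional interval is a nonparametric bootstrap
#' percentile interval (the resampling uses the current RNG state; set a
#' seed for reproducibility).
#'
#' @param risk Predicted risks (any strictly monotone transform gives the
#'   same value).
#' @param outcome Binary outcomes; both classes must be present.
#' @param conf_int Also return a bootstrap percentile interval?
#' @param boot Number of bootstrap resamples (default 2000).
#' @param conf_level Interval coverage (default 0.95).
#' @return A scalar, or with `conf_int = TRUE` a one-row tibble
#'   `estimate`, `conf_low`, `conf_high`, `boot`.
#' @export
c_statistic <- function(risk, outcome, conf_int = FALSE, boot = 2000,
                        conf_level = 0.95) {
  y <- check_binary_outcome(outcome)
  if (length(risk) != length(y)) abort("`risk` and `outcome` lengths differ.")
  est <- c_stat_ranks(risk, y)
  if (!conf_int) return(est)
  n <- length(y)
  stats <- vapply(seq_len(boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    yb <- y[i]
    if (length(unique(yb)) < 2L) return(NA_real_)
    c_stat_ranks(risk[i], yb)
  }, numeric(1))
  a <- (1 - conf_level) / 2
  qs <- quantile(stats, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  tibble::tibble(estimate = est, conf_low = qs[1], conf_high = qs[2],
                 boot = boot)
}

c_stat_ranks <- function(risk, y) {
  r <- rank(risk)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted risk and binary outcome.
#'
#' @inheritParams c_statistic
#' @return Scalar in `[0, 1]`.
#' @export
brier_score <- function(risk, outcome) {
  y <- check_binary_outcome(outcome, require_both = FALSE)
  if (length(risk) != length(y)) abort("`risk` and `outcome` lengths differ.")
  mean((risk - y)^2)
}

#' Predicted-to-observed ratio
#'
#' Mean predicted risk divided by the observed event proportion; 1 for a
#' model refit on the evaluation data, above 1 under systematic
#' overprediction.
#'
#' @inheritParams c_statistic
#' @return Positive scalar. Errors when no events are observed.
#' @export
predicted_to_observed <- function(risk, outcome) {
  y <- check_binary_outcome(outcome, require_both = FALSE)
  if (length(risk) != length(y)) abort("`risk` and `outcome` lengths differ.")
  if (sum(y) == 0) abort("Predicted-to-observed ratio is undefined with zero observed events.")
  mean(risk) / mean(y)
}

calib_glm <- function(formula, data) {
  fit <- suppressWarnings(glm(formula, data = data, family = binomial(),
                              control = glm.control(epsilon = 1e-10,
                                                    maxit = 100)))
  if (!fit$converged || any(abs(coef(fit)) > 40)) {
    abort(paste0("Logistic calibration fit did not converge (possible perfect ",
                 "separation after ", fit$iter, " IRLS iterations); consider ",
                 "a penalized fit."))
  }
  fit
}

#' Calibration intercept and slope on the log-odds scale
#'
#' The calibration slope is the coefficient of a logistic regression of the
#' outcome on the prognostic index (logit of the predicted risk); the
#' calibration intercept (calibration-in-the-large) is the intercept of the
#' same regression with the slope fixed at 1 (offset form). Perfect
#' calibration gives intercept 0 and slope 1; a negative intercept signals
#' systematic overprediction. Risks are clipped to `[1e-12, 1 - 1e-12]`
#' before the log-odds transform.
#'
#' The verbal "difference between mean observed and mean predicted risk"
#' version of calibration-in-the-large lives on the probability scale and is
#' exposed separately as [calibration_mean_difference()]; reported
#' calibration intercepts here are on the log-odds scale, the scale on which
#' recalibration operates.
#'
#' @inheritParams c_statistic
#' @return One-row tibble: `intercept`, `slope`.
#' @export
calibration_intercept_slope <- function(risk, outcome) {
  y <- check_binary_outcome(outcome)
  if (length(risk) != length(y)) abort("`risk` and `outcome` lengths differ.")
  pi <- qlogis(clip_risk(risk))
  d <- data.frame(y = y, pi = pi)
  slope <- unname(coef(calib_glm(y ~ pi, d))["pi"])
  intercept <- unname(coef(calib_glm(y ~ offset(pi), d))[1])
  tibble::tibble(intercept = intercept, slope = slope)
}

#' Calibration-in-the-large on the probability scale
#'
#' Mean observed risk minus mean predicted risk: negative under systematic
#' overprediction. See [calibration_intercept_slope()] for the log-odds
#' version used in the validation report.
#'
#' @inheritParams c_statistic
#' @return Scalar in `[-1, 1]`.
#' @export
calibration_mean_difference <- function(risk, outcome) {
  y <- check_binary_outcome(outcome, require_both = FALSE)
  mean(y) - mean(risk)
}

#' Decile calibration table
#'
#' Subjects are ranked by predicted risk (stable ordering) and split into
#' `groups` equal-count groups by rank; when the cohort size is not a
#' multiple of `groups`, the remainder subjects are allocated to the
#' lowest-risk groups. Ties in risk are kept in input order, so all groups
#' exist even when every risk is identical, and group sizes always sum to
#' the cohort size.
#'
#' @inheritParams c_statistic
#' @param groups Number of groups (default 10, i.e. deciles).
#' @return Tibble: `group`, `n`, `mean_predicted`, `observed` (event
#'   proportion). `mean_predicted` is nondecreasing across groups.
#' @export
risk_deciles <- function(risk, outcome, groups = 10) {
  y <- check_binary_outcome(outcome, require_both = FALSE)
  n <- length(risk)
  if (length(y) != n) abort("`risk` and `outcome` lengths differ.")
  if (n < groups) {
    abort(paste0("Need at least ", groups, " subjects for a ", groups,
                 "-group calibration table."))
  }
  ord <- order(risk) # stable in base R
  base <- n %/% groups
  rem <- n %% groups
  sizes <- base + as.integer(seq_len(groups) <= rem)
  grp <- rep(seq_len(groups), times = sizes)
  tibble::tibble(risk = risk[ord], y = y[ord], group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_predicted = mean(.data$risk),
                     observed = mean(.data$y),
                     .groups = "drop")
}

#' Validate a model's predictions against observed outcomes
#'
#' Runs the full external-validation panel for one model on one cohort:
#' C statistic (discrimination), Brier score, predicted-to-observed ratio,
#' calibration intercept and slope, and the decile calibration table.
#'
#' @param data Cohort table supplying the model's predictors and the outcome
#'   column.
#' @param model A [model_spec()].
#' @param outcome Outcome column (tidy-eval); defaults to the model's
#'   declared outcome.
#' @param conf_int Bootstrap an interval for the C statistic?
#' @param boot Bootstrap resamples when `conf_int = TRUE`.
#' @return A `validation_report`: use [glance()] for the one-row metric
#'   summary, [tidy()] for the decile table, [autoplot()] for the
#'   calibration plot.
#' @export
validate_model <- function(data, model, outcome = NULL, conf_int = FALSE,
                           boot = 2000) {
  outcome_q <- enquo(outcome)
  outcome_name <- if (rlang::quo_is_null(outcome_q)) model$outcome
                  else as_name(outcome_q)
  if (!outcome_name %in% names(data)) {
    abort(paste0("Cohort is missing outcome column `", outcome_name, "`."))
  }
  scored <- score_cohort(data, model)
  y <- check_binary_outcome(scored[[outcome_name]])
  risk <- scored$.risk
  cs <- c_statistic(risk, y, conf_int = conf_int, boot = boot)
  calib <- calibration_intercept_slope(risk, y)
  structure(
    list(
      model_name = model$name, outcome = outcome_name,
      n = length(y), n_events = sum(y),
      c_statistic = if (conf_int) cs$estimate else cs,
      c_conf_low = if (conf_int) cs$conf_low else NA_real_,
      c_conf_high = if (conf_int) cs$conf_high else NA_real_,
      brier = brier_score(risk, y),
      predicted_to_observed = predicted_to_observed(risk, y),
      calibration_intercept = calib$intercept,
      calibration_slope = calib$slope,
      calibration_mean_difference = calibration_mean_difference(risk, y),
      deciles = risk_deciles(risk, y)
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> model ", x$model_name, " on n = ", x$n,
      " (", x$n_events, " events)\n", sep = "")
  cat(sprintf("  C statistic            %.3f\n", x$c_statistic))
  if (!is.na(x$c_conf_low)) {
    cat(sprintf("    bootstrap 95%% CI     (%.3f, %.3f)\n",
                x$c_conf_low, x$c_conf_high))
  }
  cat(sprintf("  Brier score            %.4f\n", x$brier))
  cat(sprintf("  Predicted:observed     %.3f\n", x$predicted_to_observed))
  cat(sprintf("  Calibration intercept  %.3f\n", x$calibration_intercept))
  cat(sprintf("  Calibration slope      %.3f\n", x$calibration_slope))
  invisible(x)
}

#' @describeIn validate_model One-row tibble of the validation metrics.
#' @param x A `validation_report`.
#' @param ... Unused.
#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    model = x$model_name, n = x$n, n_events = x$n_events,
    c_statistic = x$c_statistic, c_conf_low = x$c_conf_low,
    c_conf_high = x$c_conf_high, brier = x$brier,
    predicted_to_observed = x$predicted_to_observed,
    calibration_intercept = x$calibration_intercept,
    calibration_slope = x$calibration_slope,
    calibration_mean_difference = x$calibration_mean_difference
  )
}

#' @describeIn validate_model Decile calibration table
#'   (`group`, `n`, `mean_predicted`, `observed`).
#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) x$deciles

#' @describeIn validate_model Calibration plot: observed event proportion
#'   against mean predicted risk within tenths of increasing predicted risk,
#'   with the line of perfect agreement dashed.
#' @param object A `validation_report`.
#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  ggplot2::ggplot(object$deciles,
                  ggplot2::aes(x = .data$mean_predicted, y = .data$observed)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, NA), ylim = c(0, NA)) +
    ggplot2::labs(
      x = "Mean predicted risk (by tenth of predicted risk)",
      y = "Observed event proportion",
      title = paste0("Calibration: ", object$model_name),
      subtitle = sprintf("n = %d; P:O = %.2f; intercept = %.2f; slope = %.2f",
                         object$n, object$predicted_to_observed,
                         object$calibration_intercept,
                         object$calibration_slope)
    ) +
    ggplot2::theme_minimal()
}
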