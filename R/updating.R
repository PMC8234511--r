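update_provenance <- function(method, data, fit, extra = list()) {
  c(list(method = method,
         n = nrow(data),
         cohort_hash = rlang::hash(data),
         converged = fit$converged,
         iterations = fit$iter,
         deviance = unname(fit$deviance)),
    extra)
}

fit_or_fail <- function(formula, data, what) {
  fit <- suppressWarnings(glm(formula, data = data, family = binomial(),
                              control = glm.control(epsilon = 1e-10,
                                                    maxit = 100)))
  if (!fit$converged) {
    abort(paste0(what, " did not converge after ", fit$iter,
                 " IRLS iterations (deviance ", format(fit$deviance),
                 "); possible separation."))
  }
  if (any(abs(coef(fit)) > 40, na.rm = TRUE)) {
    abort(paste0(what, " shows signs of perfect separation (|coefficient| > 40 ",
                 "after ", fit$iter, " iterations)."))
  }
  fit
}

#' Update a model for a new population by logistic recalibration
#'
#' Fits a logistic regression of the observed outcome on the model's
#' prognostic index as the only covariate, giving a calibration intercept
#' `a` and slope `b`, then rescales the model: every coefficient is
#' multiplied by `b` and the intercept becomes `a + b * intercept`. The
#' recalibrated model's predictions on this cohort therefore have
#' calibration intercept 0 and slope 1, while discrimination is unchanged
#' (the transform is monotone).
#'
#' @param model A [model_spec()].
#' @param data Cohort with the model's predictors and outcome; both outcome
#'   classes must be present.
#' @param outcome Outcome column (tidy-eval); defaults to the model's
#'   declared outcome.
#' @return A new [model_spec()] with provenance recording the method,
#'   cohort hash, fitted `(a, b)` and fit diagnostics.
#' @export
recalibrate <- function(model, data, outcome = NULL) {
  outcome_q <- enquo(outcome)
  outcome_name <- if (rlang::quo_is_null(outcome_q)) model$outcome
                  else as_name(outcome_q)
  if (!outcome_name %in% names(data)) {
    abort(paste0("Cohort is missing outcome column `", outcome_name, "`."))
  }
  y <- check_binary_outcome(data[[outcome_name]])
  d <- data.frame(y = y, pi = linear_predictor(data, model))
  fit <- fit_or_fail(y ~ pi, d, "Logistic recalibration")
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)["pi"])
  terms <- model$terms
  terms$coefficient <- terms$coefficient * b
  terms$odds_ratio <- exp(terms$coefficient)
  model_spec(
    name = paste0(model$name, "_recalibrated"),
    label = paste0(model$label, " (recalibrated)"),
    outcome = model$outcome,
    intercept = a + b * model$intercept,
    terms = terms,
    notes = model$notes,
    provenance = update_provenance("logistic_recalibration", data, fit,
                                   list(calibration_intercept = a,
                                        calibration_slope = b,
                                        parent = model$name))
  )
}

#' Refit a model's term structure de novo on a new cohort
#'
#' Maximum-likelihood logistic regression over exactly the original model's
#' term structure - the same predictors, codings, scale divisors and
#' polynomial terms, and nothing else - so that any performance change
#' reflects re-estimation, not added variables. By construction the refitted
#' model evaluated on the fitting cohort has calibration intercept 0,
#' slope 1 and predicted-to-observed ratio 1 (the maximum-likelihood score
#' equations).
#'
#' @inheritParams recalibrate
#' @return A new [model_spec()] with re-estimated coefficients and
#'   provenance. Rank deficiency (for instance an empty categorical level)
#'   raises an error naming the offending term.
#' @export
refit <- function(model, data, outcome = NULL) {
  outcome_q <- enquo(outcome)
  outcome_name <- if (rlang::quo_is_null(outcome_q)) model$outcome
                  else as_name(outcome_q)
  if (!outcome_name %in% names(data)) {
    abort(paste0("Cohort is missing outcome column `", outcome_name, "`."))
  }
  y <- check_binary_outcome(data[[outcome_name]])
  X <- model_matrix(data, model)
  d <- data.frame(y = y, X)
  colnames(d) <- c("y", paste0("t", seq_len(ncol(X))))
  f <- stats::as.formula(paste("y ~", paste(colnames(d)[-1], collapse = " + ")))
  fit <- fit_or_fail(f, d, paste0("Refit of `", model$name, "`"))
  beta <- coef(fit)
  if (anyNA(beta)) {
    bad <- term_label(model$terms)[is.na(beta[-1])]
    abort(paste0("Refit is rank deficient; inestimable term(s): ",
                 paste(bad, collapse = ", "),
                 " (e.g. an empty categorical level)."))
  }
  terms <- model$terms
  terms$coefficient <- unname(beta[-1])
  terms$odds_ratio <- exp(terms$coefficient)
  model_spec(
    name = paste0(model$name, "_refit"),
    label = paste0(model$label, " (refitted)"),
    outcome = model$outcome,
    intercept = unname(beta[1]),
    terms = terms,
    notes = model$notes,
    provenance = update_provenance("refit", data, fit,
                                   list(parent = model$name))
  )
}
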