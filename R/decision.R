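#' Follow-up decision strategies
#'
#' A decision strategy deterministically maps each subject to treat / not
#' treat (here, "treat" means targeting the subject for post-discharge
#' follow-up). Available constructors:
#'
#' * `model_strategy(model)` — treat when the model's predicted risk is at
#'   least the threshold probability under evaluation (boundary inclusive);
#'   re-thresholded at every grid point of a decision curve.
#' * `treat_all()`, `treat_none()` — the two reference strategies.
#' * `rule_strategy(condition, label)` — treat when a covariate predicate
#'   holds; `condition` is a tidy-eval expression on cohort columns.
#' * `strategy_any_aki()` — any AKI (`aki_stage != "0"`).
#' * `strategy_aki_stage_2_3()` — AKI stage 2 or 3.
#' * `strategy_discharge_egfr_lt_30()` — discharge eGFR < 30 mL/min/1.73m^2,
#'   a pragmatic proxy for non-recovery of kidney function.
#'
#' @param model A [model_spec()].
#' @param label Legend label.
#' @param condition Logical expression evaluated on the cohort.
#' @return An object of class `decision_strategy`.
#' @export
model_strategy <- function(model, label = model$name) {
  structure(list(type = "model", model = model, label = label),
            class = "decision_strategy")
}

#' @rdname model_strategy
#' @export
treat_all <- function(label = "Treat all") {
  structure(list(type = "all", label = label), class = "decision_strategy")
}

#' @rdname model_strategy
#' @export
treat_none <- function(label = "Treat none") {
  structure(list(type = "none", label = label), class = "decision_strategy")
}

#' @rdname model_strategy
#' @export
rule_strategy <- function(condition, label) {
  structure(list(type = "rule", condition = enquo(condition), label = label),
            class = "decision_strategy")
}

#' @rdname model_strategy
#' @export
strategy_any_aki <- function(label = "Any AKI") {
  rule_strategy(as.character(.data$aki_stage) != "0", label)
}

#' @rdname model_strategy
#' @export
strategy_aki_stage_2_3 <- function(label = "AKI stage 2 or 3") {
  rule_strategy(as.character(.data$aki_stage) %in% c("2", "3"), label)
}

#' @rdname model_strategy
#' @export
strategy_discharge_egfr_lt_30 <- function(label = "Discharge eGFR < 30") {
  rule_strategy(.data$discharge_egfr < 30, label)
}

#' @export
print.decision_strategy <- function(x, ...) {
  cat("<decision_strategy> ", x$label, " [", x$type, "]\n", sep = "")
  invisible(x)
}

check_threshold <- function(threshold) {
  if (any(threshold <= 0) || any(threshold >= 1)) {
    abort("Threshold probabilities must lie strictly inside (0, 1).")
  }
  threshold
}

treat_indicator <- function(strategy, data, threshold) {
  stopifnot(inherits(strategy, "decision_strategy"))
  out <- switch(strategy$type,
    all = rep(TRUE, nrow(data)),
    none = rep(FALSE, nrow(data)),
    model = score_cohort(data, strategy$model)$.risk >= threshold,
    rule = {
      v <- eval_tidy(strategy$condition, data)
      if (!is.logical(v)) abort("A rule strategy must evaluate to logical.")
      v
    }
  )
  if (anyNA(out) || length(out) != nrow(data)) {
    abort("Strategy produced missing or wrong-length treat decisions.")
  }
  out
}

nb_from_counts <- function(tp, fp, n, threshold) {
  tp / n - (fp / n) * (threshold / (1 - threshold))
}

#' Net benefit of a decision strategy at a threshold probability
#'
#' `NB = TP/n - (FP/n) * (pt / (1 - pt))`: the true-positive rate minus the
#' false-positive rate weighted by the odds of the threshold probability
#' `pt`, which encodes the harm-benefit tradeoff of intervening. Treat-none
#' has net benefit 0 by construction; net benefit never exceeds the event
#' prevalence.
#'
#' @param data Cohort table.
#' @param strategy A [model_strategy()] / [rule_strategy()] / [treat_all()] /
#'   [treat_none()].
#' @param outcome Outcome column (tidy-eval).
#' @param threshold Threshold probability in (0, 1); model strategies treat
#'   at `risk >= threshold`.
#' @return Scalar net benefit.
#' @export
net_benefit <- function(data, strategy, outcome, threshold) {
  classification_table(data, strategy, {{ outcome }}, threshold)$net_benefit
}

#' 2x2 classification of a decision strategy at a threshold
#'
#' Cross-classifies treat decisions against observed outcomes, with the
#' percentage correctly classified and the net benefit at the stated
#' threshold.
#'
#' @inheritParams net_benefit
#' @return One-row tibble: `strategy`, `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `n`, `percent_correct`, `net_benefit`.
#' @export
classification_table <- function(data, strategy, outcome, threshold) {
  check_threshold(threshold)
  y <- check_binary_outcome(eval_tidy(enquo(outcome), data),
                            require_both = FALSE)
  if (length(y) != nrow(data)) abort("Outcome length must match the cohort.")
  treat <- treat_indicator(strategy, data, threshold)
  tp <- sum(treat & y == 1)
  fp <- sum(treat & y == 0)
  fn <- sum(!treat & y == 1)
  tn <- sum(!treat & y == 0)
  n <- length(y)
  tibble::tibble(
    strategy = strategy$label, threshold = threshold,
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    percent_correct = 100 * (tp + tn) / n,
    net_benefit = nb_from_counts(tp, fp, n, threshold)
  )
}

#' Decision curve: net benefit across a threshold grid
#'
#' Evaluates each strategy's net benefit over a grid of threshold
#' probabilities. Model strategies are re-thresholded at every grid point;
#' covariate rules and treat-all/none do not depend on the threshold except
#' through the false-positive weight. The default grid, 0.01 to 0.50 in
#' steps of 0.01, covers the prespecified decision thresholds (1% and 10%
#' for CKD progression follow-up, 30% for readmission follow-up).
#'
#' @inheritParams net_benefit
#' @param strategies List of strategies (a single strategy is accepted).
#' @param thresholds Numeric grid strictly inside (0, 1).
#' @return A tibble of class `decision_curve`: `strategy`, `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `n`, `percent_correct`, `net_benefit`.
#'   Plot with [autoplot()].
#' @export
decision_curve <- function(data, strategies, outcome,
                           thresholds = seq(0.01, 0.50, by = 0.01)) {
  if (inherits(strategies, "decision_strategy")) strategies <- list(strategies)
  if (!length(strategies)) abort("Provide at least one decision strategy.")
  check_threshold(thresholds)
  labels <- vapply(strategies, `[[`, character(1), "label")
  if (anyDuplicated(labels)) abort("Strategy labels must be unique.")
  out <- purrr::map_dfr(strategies, function(s) {
    purrr::map_dfr(thresholds, function(pt) {
      classification_table(data, s, {{ outcome }}, pt)
    })
  })
  out$strategy <- factor(out$strategy, levels = labels)
  class(out) <- c("decision_curve", class(out))
  out
}

#' @describeIn decision_curve Decision-curve plot: one net-benefit line per
#'   strategy against threshold probability.
#' @param object A `decision_curve`.
#' @param ... Unused.
#' @method autoplot decision_curve
#' @export
autoplot.decision_curve <- function(object, ...) {
  prev <- max(object$tp + object$fn) / max(object$n)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$threshold, y = .data$net_benefit,
                               colour = .data$strategy)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(-0.05, prev * 1.1)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' False positives traded per true positive at a threshold
#'
#' `(1 - pt) / pt`: the number of false-positive follow-ups a clinician
#' accepts to find one true positive when the threshold probability is
#' `pt`. At `pt = 0.1` the exchange rate is 9.
#'
#' @param threshold Threshold probability strictly inside (0, 1).
#' @return Scalar (vectorized over `threshold`).
#' @export
exchange_rate <- function(threshold) {
  check_threshold(threshold)
  (1 - threshold) / threshold
}
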