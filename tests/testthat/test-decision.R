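# 100-subject cohort with 20 events and a known risk split used for
# hand-tabulated 2x2 checks: 30 treated under the model at pt = 0.3,
# 10 of them events.
hand_cohort <- function() {
  tibble::tibble(
    risk = c(rep(0.6, 30), rep(0.1, 70)),
    y = c(rep(1, 10), rep(0, 20), rep(1, 10), rep(0, 60)),
    aki_stage = rep(c("0", "1"), 50)
  )
}

risk_model <- function() {
  # identity "model": a single continuous term with coefficient 1 on the
  # logit of a risk column
  model_spec("risk_passthrough", outcome = "y", intercept = 0,
             terms = tibble::tibble(predictor = "pi_col", type = "continuous",
                                    scale = 1, degree = 1, coefficient = 1))
}

test_that("exchange rate is the odds of the threshold probability", {
  expect_identical(exchange_rate(0.1), 9)
  expect_identical(exchange_rate(0.5), 1)
  expect_equal(exchange_rate(0.3), 7 / 3)
  expect_error(exchange_rate(0), "inside")
  expect_error(exchange_rate(1), "inside")
})

test_that("net benefit follows the TP/FP weighting formula", {
  d <- hand_cohort()
  d$pi_col <- qlogis(d$risk)
  m <- model_strategy(risk_model(), "Model")

  # treat-none: identically zero
  for (pt in c(0.05, 0.2, 0.45)) {
    expect_identical(net_benefit(d, treat_none(), y, pt), 0)
  }

  # hand evaluation: TP=10, FP=20 of n=100 at pt=0.1 (risk 0.6 >= 0.1 >
  # 0.1? no: both groups >= 0.1) -- use pt=0.3 so only the 0.6 group treats
  expect_equal(net_benefit(d, m, y, 0.3),
               10 / 100 - (20 / 100) * (0.3 / 0.7))

  # treat-all with prevalence 0.2 at pt=0.1: 0.2 - 0.8/9
  expect_equal(net_benefit(d, treat_all(), y, 0.1), 0.2 - 0.8 * (0.1 / 0.9))
  # at threshold = prevalence, treat-all net benefit is zero
  expect_equal(net_benefit(d, treat_all(), y, 0.2), 0, tolerance = 1e-12)
})

test_that("classification tables cross-tabulate decisions against outcomes", {
  d <- hand_cohort()
  ta <- classification_table(d, treat_all(), y, 0.3)
  expect_equal(ta[, c("tp", "fp", "tn", "fn")],
               tibble::tibble(tp = 20L, fp = 80L, tn = 0L, fn = 0L))
  expect_equal(ta$percent_correct, 20)

  tn <- classification_table(d, treat_none(), y, 0.3)
  expect_equal(tn[, c("tp", "fp", "tn", "fn")],
               tibble::tibble(tp = 0L, fp = 0L, tn = 80L, fn = 20L))
  expect_equal(tn$percent_correct, 80)

  # model strategy on a hand-built 10-subject cohort at pt = 0.3
  d10 <- tibble::tibble(
    pi_col = qlogis(c(0.9, 0.8, 0.35, 0.3, 0.29, 0.2, 0.1, 0.05, 0.5, 0.01)),
    y = c(1, 0, 1, 0, 1, 0, 0, 0, 1, 0)
  )
  m <- model_strategy(risk_model(), "Model")
  tab <- classification_table(d10, m, y, 0.3)
  # treated: risks 0.9 0.8 0.35 0.3 0.5 (boundary inclusive) -> TP 3, FP 2
  expect_equal(tab$tp, 3L)
  expect_equal(tab$fp, 2L)
  expect_equal(tab$fn, 1L)
  expect_equal(tab$tn, 4L)
  expect_equal(tab$net_benefit, 3 / 10 - (2 / 10) * (3 / 7))
})

test_that("covariate-rule strategies map cohort columns to decisions", {
  d <- tibble::tibble(
    aki_stage = c("0", "1", "2", "3"),
    discharge_egfr = c(50, 25, 40, 20),
    y = c(0, 0, 1, 1)
  )
  expect_equal(classification_table(d, strategy_any_aki(), y, 0.2)$tp +
                 classification_table(d, strategy_any_aki(), y, 0.2)$fp, 3L)
  t23 <- classification_table(d, strategy_aki_stage_2_3(), y, 0.2)
  expect_equal(c(t23$tp, t23$fp), c(2L, 0L))
  teg <- classification_table(d, strategy_discharge_egfr_lt_30(), y, 0.2)
  expect_equal(c(teg$tp, teg$fp), c(1L, 1L))
  expect_error(
    net_benefit(d, rule_strategy(.data$discharge_egfr, "bad"), y, 0.2),
    "logical"
  )
})

test_that("decision curves agree with single-threshold evaluation over the grid", {
  coh <- simulate_cohort(grampian_cohort_config(n = 2000), seed = 50)
  strategies <- list(
    model_strategy(load_model("synthetic_grampian_truth"), "Model"),
    strategy_any_aki(), strategy_aki_stage_2_3(), treat_all(), treat_none()
  )
  grid <- seq(0.05, 0.45, by = 0.05)
  dc <- decision_curve(coh, strategies, death_or_readmission_90d,
                       thresholds = grid)
  expect_equal(nrow(dc), length(strategies) * length(grid))

  # counts-vs-formula internal consistency for every row
  expect_equal(dc$net_benefit,
               dc$tp / dc$n - (dc$fp / dc$n) * (dc$threshold / (1 - dc$threshold)))
  # conservation of the 2x2
  expect_true(all(dc$tp + dc$fp + dc$tn + dc$fn == dc$n))
  # net benefit never exceeds prevalence
  prev <- mean(coh$death_or_readmission_90d)
  expect_true(all(dc$net_benefit <= prev + 1e-12))
  # treat-none series identically zero
  expect_true(all(dc$net_benefit[dc$strategy == "Treat none"] == 0))

  expect_s3_class(autoplot(dc), "ggplot")
  expect_error(decision_curve(coh, list(), death_or_readmission_90d),
               "at least one")
})

test_that("a perfectly informative model dominates every strategy at all thresholds", {
  set.seed(51)
  d <- tibble::tibble(
    y = rbinom(400, 1, 0.3),
    aki_stage = sample(c("0", "1", "2", "3"), 400, replace = TRUE)
  )
  d$pi_col <- qlogis(ifelse(d$y == 1, 1 - 1e-9, 1e-9))
  strategies <- list(model_strategy(risk_model(), "Oracle model"),
                     strategy_any_aki(), treat_all(), treat_none())
  dc <- decision_curve(d, strategies, y, thresholds = seq(0.05, 0.45, 0.1))
  wide <- tidyr::pivot_wider(dc[, c("strategy", "threshold", "net_benefit")],
                             names_from = "strategy",
                             values_from = "net_benefit")
  expect_true(all(wide$`Oracle model` >= wide$`Any AKI` - 1e-12))
  expect_true(all(wide$`Oracle model` >= wide$`Treat all` - 1e-12))
  expect_true(all(wide$`Oracle model` >= 0))
})
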