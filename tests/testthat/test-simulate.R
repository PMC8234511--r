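test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- grampian_cohort_config(n = 200)
  a <- simulate_cohort(cfg, seed = 70)
  b <- simulate_cohort(cfg, seed = 70)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(cfg, seed = 71)))

  s1 <- simulate_creatinine_series(30, seed = 70)
  s2 <- simulate_creatinine_series(30, seed = 70)
  expect_identical(s1, s2)

  p1 <- simulate_care_pathways(a, seed = 70)
  p2 <- simulate_care_pathways(a, seed = 70)
  expect_identical(p1, p2)

  # the generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_cohort(cfg, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("cohort marginals match the configured parameters at scale", {
  cfg <- grampian_cohort_config(n = 20000)
  coh <- simulate_cohort(cfg, seed = 72)
  expect_equal(mean(coh$age), 60.9, tolerance = 0.02)
  expect_equal(stats::sd(coh$age), 19.8, tolerance = 0.05)
  expect_equal(mean(coh$emergency_admission), 0.713, tolerance = 0.02)
  expect_equal(unname(prop.table(table(coh$aki_stage))["1"]), 0.0865,
               tolerance = 0.1)
  expect_equal(mean(coh$baseline_egfr), 86.3, tolerance = 0.02)
  # outcome prevalence hits its target (2,927 / 26,575)
  expect_equal(mean(coh$death_or_readmission_90d), 2927 / 26575,
               tolerance = 0.05)

  ca <- alberta_cohort_config(n = 20000)
  coha <- simulate_cohort(ca, seed = 73)
  expect_equal(mean(coha$female), 0.458, tolerance = 0.03)
  expect_equal(mean(coha$ckd_g45_1y), 140 / 9382, tolerance = 0.15)
})

test_that("generated outcomes follow the configured logistic law", {
  # slope_factor 1, shift 0: refit recovers the true coefficients
  cfg <- grampian_cohort_config(n = 40000)
  cfg$target_prevalence <- NULL
  cfg$intercept_shift <- 0
  coh <- simulate_cohort(cfg, seed = 74)
  truth <- load_model("synthetic_grampian_truth")
  rf <- refit(truth, coh)
  expect_equal(rf$terms$coefficient, truth$terms$coefficient,
               tolerance = 0.15)
  expect_equal(rf$intercept, truth$intercept, tolerance = 0.1)

  # negative shift: overprediction in the configured direction, P:O > 1
  shifted <- simulate_external_shift(coh, truth, shift = -0.7, seed = 75)
  expect_lt(mean(shifted$death_or_readmission_90d),
            mean(score_cohort(shifted, truth)$.risk))
  expect_gt(predicted_to_observed(score_cohort(shifted, truth)$.risk,
                                  shifted$death_or_readmission_90d), 1)

  # slope_factor 0.9 is recovered as the fitted calibration slope
  sloped <- simulate_external_shift(coh, truth, shift = 0,
                                    slope_factor = 0.9, seed = 76)
  cal <- calibration_intercept_slope(score_cohort(sloped, truth)$.risk,
                                     sloped$death_or_readmission_90d)
  expect_equal(cal$slope, 0.9, tolerance = 0.05)

  # target_po solves the shift by bisection
  po2 <- simulate_external_shift(coh, truth, seed = 77, target_po = 2)
  expect_equal(predicted_to_observed(score_cohort(po2, truth)$.risk,
                                     po2$death_or_readmission_90d),
               2, tolerance = 0.1)
})

test_that("creatinine generator and grampian detector agree case by case", {
  ser <- simulate_creatinine_series(1000, seed = 78)
  det <- purrr::map_dfr(ser$observations, detect_aki_grampian,
                        admission = c(0, 4))
  expect_equal(det$stage, ser$truth_stage)
  expect_equal(det$criterion, ser$truth_criterion)
  expect_equal(det$flag, ser$truth_flag)

  none <- simulate_creatinine_series(200, seed = 79, aki_fraction = 0)
  det0 <- purrr::map_dfr(none$observations, detect_aki_grampian,
                         admission = c(0, 4))
  expect_true(all(!det0$flag))

  expect_error(
    simulate_creatinine_series(10, seed = 80, stage_mix = c(0, 0.5, 0.5),
                               criterion_mix = c(delta48h = 1, ratio7d = 0,
                                                 ratio8_90d = 0,
                                                 ratio91_365d = 0)),
    "Infeasible"
  )
})

test_that("pathway generator respects monitoring probabilities at the extremes", {
  coh <- simulate_cohort(grampian_cohort_config(n = 800), seed = 81)
  never <- simulate_care_pathways(coh, pathway_params(monitoring_prob = 0),
                                  seed = 82)
  expect_equal(unmonitored_outcomes(never)$fraction_unmonitored, 1)
  always <- simulate_care_pathways(coh, pathway_params(monitoring_prob = 1),
                                   seed = 83)
  expect_equal(unmonitored_outcomes(always)$fraction_unmonitored, 0)
})

test_that("invalid configurations are rejected up front", {
  cfg <- grampian_cohort_config(n = 10)
  cfg$covariates$rural$p <- 1.4
  expect_error(do.call(cohort_config,
                       cfg[c("n", "covariates", "true_model",
                             "target_prevalence")]),
               "\\[0, 1\\]")
  expect_error(cohort_config(10, list(), load_model("aberdeen_original"),
                             slope_factor = 0),
               "positive")
  expect_error(pathway_params(monitoring_prob = 1.2))
  expect_error(simulate_creatinine_series(5, seed = 1, aki_fraction = 2),
               "aki_fraction")
})
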