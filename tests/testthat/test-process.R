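test_that("event-log validation enforces the structural invariants", {
  expect_s3_class(validate_event_log(toy_event_log()), "tbl_df")
  expect_equal(nrow(validate_event_log(toy_event_log()[0, ])), 0L)

  no_discharge <- tibble::tibble(case_id = "x", activity = "gp_monitoring",
                                 day = 3)
  expect_error(validate_event_log(no_discharge), "x")

  after_terminal <- dplyr::bind_rows(
    toy_event_log(),
    tibble::tibble(case_id = "a", activity = "gp_monitoring", day = 20)
  )
  expect_error(validate_event_log(after_terminal), "after")

  unknown <- dplyr::mutate(toy_event_log(),
                           activity = replace(activity, 2, "pharmacy"))
  expect_error(validate_event_log(unknown), "pharmacy")

  # same-day ties resolve monitoring before terminal events
  tied <- tibble::tibble(case_id = "t",
                         activity = c("discharge", "readmission",
                                      "gp_monitoring"),
                         day = c(0, 7, 7))
  ordered <- validate_event_log(tied)
  expect_equal(ordered$activity, c("discharge", "gp_monitoring",
                                   "readmission"))
})

test_that("horizon truncation drops late events and closes open cases", {
  log <- tibble::tibble(
    case_id = c("a", "a", "b", "b", "c"),
    activity = c("discharge", "readmission", "discharge", "gp_monitoring",
                 "discharge"),
    day = c(0, 40, 0, 10, 0)
  )
  t30 <- truncate_to_horizon(log, horizon = 30)
  a <- t30[t30$case_id == "a", ]
  expect_equal(a$activity, c("discharge", "end_follow_up"))
  expect_equal(a$day[2], 30)
  b <- t30[t30$case_id == "b", ]
  expect_equal(tail(b$activity, 1), "end_follow_up")

  # terminal inside the horizon is untouched, no synthetic exit added
  log2 <- tibble::tibble(case_id = "d",
                         activity = c("discharge", "readmission"),
                         day = c(0, 13))
  t90 <- truncate_to_horizon(log2, horizon = 90)
  expect_equal(t90$activity, c("discharge", "readmission"))

  expect_equal(nrow(truncate_to_horizon(toy_event_log()[0, ], 30)), 0L)
})

test_that("directly-follows map reproduces a manual trace of the toy log", {
  pm <- directly_follows(toy_event_log())
  e <- pm$edges
  get <- function(from, to) e[e$from == from & e$to == to, ]
  expect_equal(get("discharge", "gp_monitoring")$n, 1L)
  expect_equal(get("discharge", "gp_monitoring")$median_days, 5)
  expect_equal(get("gp_monitoring", "readmission")$n, 1L)
  expect_equal(get("gp_monitoring", "readmission")$median_days, 4)
  expect_equal(get("discharge", "readmission")$n, 1L)
  expect_equal(get("discharge", "readmission")$median_days, 13)
  expect_equal(nrow(e), 3L)
  expect_equal(pm$n_cases, 2L)

  # median over an even number of durations uses the midpoint
  log2 <- dplyr::bind_rows(
    toy_event_log(),
    tibble::tibble(case_id = "c", activity = c("discharge", "readmission"),
                   day = c(0, 20))
  )
  pm2 <- directly_follows(log2)
  expect_equal(pm2$edges$median_days[pm2$edges$from == "discharge" &
                                       pm2$edges$to == "readmission"],
               (13 + 20) / 2)

  expect_error(directly_follows(
    tibble::tibble(case_id = "open", activity = c("discharge",
                                                  "gp_monitoring"),
                   day = c(0, 5))
  ), "terminal")
})

test_that("flow conservation and terminal accounting hold on simulated logs", {
  coh <- simulate_cohort(grampian_cohort_config(n = 1500), seed = 60)
  log <- simulate_care_pathways(coh, pathway_params(), seed = 61)
  pm <- directly_follows(log)
  nodes <- pm$nodes
  mid <- !nodes$terminal & nodes$activity != "discharge"
  expect_equal(nodes$incoming[mid], nodes$outgoing[mid])
  expect_equal(nodes$visits[mid], nodes$incoming[mid])
  expect_equal(sum(nodes$incoming[nodes$terminal]), pm$n_cases)
  expect_equal(nodes$outgoing[nodes$activity == "discharge"], pm$n_cases)

  # 30-day view preserves the invariants after truncation
  pm30 <- directly_follows(truncate_to_horizon(log, 30))
  n30 <- pm30$nodes
  expect_equal(sum(n30$incoming[n30$terminal]), pm30$n_cases)
})

test_that("unmonitored poor outcomes match the manual trace and the edge counts", {
  u <- unmonitored_outcomes(toy_event_log())
  expect_equal(u$n_poor_outcome, 2L)
  expect_equal(u$n_unmonitored, 1L)
  expect_equal(u$fraction_unmonitored, 0.5)
  expect_equal(u$median_days_to_outcome, 13)

  # undefined quantities are reported as absent, not as zeros
  all_mon <- tibble::tibble(
    case_id = c("a", "a", "a"),
    activity = c("discharge", "gp_monitoring", "readmission"),
    day = c(0, 3, 9)
  )
  expect_equal(unmonitored_outcomes(all_mon)$n_unmonitored, 0L)
  expect_true(is.na(unmonitored_outcomes(all_mon)$median_days_to_outcome))
  no_poor <- tibble::tibble(case_id = "a",
                            activity = c("discharge", "end_follow_up"),
                            day = c(0, 90))
  expect_true(is.na(unmonitored_outcomes(no_poor)$fraction_unmonitored))

  # consistency with the process map: unmonitored = direct discharge->terminal
  coh <- simulate_cohort(grampian_cohort_config(n = 1200), seed = 62)
  log <- simulate_care_pathways(coh, pathway_params(monitoring_prob = 0.5),
                                seed = 63)
  pm <- directly_follows(log)
  direct <- sum(pm$edges$n[pm$edges$from == "discharge" &
                             pm$edges$to %in% c("readmission", "death")])
  expect_equal(unmonitored_outcomes(log)$n_unmonitored, direct)

  # A&E can be excluded from "monitoring" by configuration
  ae_only <- tibble::tibble(
    case_id = c("z", "z", "z"),
    activity = c("discharge", "accident_emergency", "death"),
    day = c(0, 2, 8)
  )
  expect_equal(unmonitored_outcomes(ae_only)$n_unmonitored, 0L)
  expect_equal(unmonitored_outcomes(ae_only,
                                    include_ae = FALSE)$n_unmonitored, 1L)
})

test_that("event logs round-trip through ISO 8601 delimited files", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tibble::tibble(
    case_id = c("a", "a", "b", "b"),
    activity = c("discharge", "readmission", "discharge", "end_follow_up"),
    timestamp = c("2012-03-01", "2012-03-14", "2012-03-05", "2012-06-03")
  ), path, row.names = FALSE)
  log <- read_event_log(path)
  expect_equal(log$day[log$case_id == "a"], c(0, 13))
  expect_equal(log$day[log$case_id == "b"], c(0, 90))
})

test_that("process maps export to text and plot", {
  pm <- directly_follows(toy_event_log())
  txt <- process_map_text(pm)
  expect_match(txt, "digraph")
  expect_match(txt, "discharge\" -> \"gp_monitoring")
  expect_equal(nrow(tidy(pm, top_k = 2)), 2L)
  expect_s3_class(autoplot(pm), "ggplot")
})
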