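PM_ACTIVITIES <- c("discharge", "gp_monitoring", "outpatient_clinic",
                   "accident_emergency", "readmission", "death",
                   "end_follow_up")
PM_TERMINAL <- c("readmission", "death", "end_follow_up")
PM_MONITORING <- c("gp_monitoring", "outpatient_clinic", "accident_emergency")

## same-day tie-break: discharge first, monitoring contacts before terminals
activity_priority <- function(activity) {
  match(activity, PM_ACTIVITIES)
}

#' Validate and order a care-pathway event log
#'
#' An event log records post-discharge care events, one row per event:
#' `case_id`, `activity` (one of discharge, gp_monitoring,
#' outpatient_clinic, accident_emergency, readmission, death,
#' end_follow_up) and `day` (days since discharge). Each case must start
#' with exactly one discharge at day 0, events must not precede it, at most
#' one terminal event (readmission, death, end_follow_up) may occur and
#' nothing may follow it. Same-day events are ordered by a declared activity
#' priority: discharge, then monitoring contacts, then terminal events.
#'
#' @param log Event log data frame.
#' @return The log as a tibble, ordered by case, day and activity priority.
#' @export
validate_event_log <- function(log) {
  log <- tibble::as_tibble(log)
  if (nrow(log) == 0L) {
    return(tibble::tibble(case_id = character(), activity = character(),
                          day = numeric()))
  }
  if (!all(c("case_id", "activity", "day") %in% names(log))) {
    abort("An event log needs `case_id`, `activity` and `day` columns.")
  }
  bad <- setdiff(unique(log$activity), PM_ACTIVITIES)
  if (length(bad)) {
    abort(paste0("Unknown activity(ies): ", paste(bad, collapse = ", "), "."))
  }
  log <- dplyr::arrange(log, .data$case_id, .data$day,
                        activity_priority(.data$activity))
  by_case <- split(log, log$case_id)
  for (cs in by_case) {
    id <- cs$case_id[1]
    n_disch <- sum(cs$activity == "discharge")
    if (n_disch != 1L || cs$activity[1] != "discharge") {
      abort(paste0("Case `", id,
                   "` must begin with exactly one discharge event."))
    }
    if (any(cs$day < cs$day[1])) {
      abort(paste0("Case `", id, "` has events before its discharge."))
    }
    term <- which(cs$activity %in% PM_TERMINAL)
    if (length(term) > 1L || (length(term) == 1L && term != nrow(cs))) {
      abort(paste0("Case `", id,
                   "` has events after (or multiple) terminal events."))
    }
  }
  log
}

#' Read an event log from a delimited file
#'
#' Expects columns `case_id`, `activity`, `timestamp` (ISO 8601 date or
#' datetime). Timestamps are converted to days elapsed since each case's
#' discharge event.
#'
#' @param path Path to a CSV file.
#' @return A validated event log tibble (`case_id`, `activity`, `day`).
#' @export
read_event_log <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("case_id", "activity", "timestamp") %in% names(raw))) {
    abort("Event log files need `case_id`, `activity`, `timestamp` columns.")
  }
  t <- as.POSIXct(raw$timestamp, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                 "%Y-%m-%d"))
  if (anyNA(t)) abort("Unparseable ISO 8601 timestamps in event log.")
  log <- tibble::tibble(case_id = as.character(raw$case_id),
                        activity = raw$activity,
                        time = as.numeric(t) / 86400)
  log <- log |>
    dplyr::group_by(.data$case_id) |>
    dplyr::mutate(day = .data$time -
                    .data$time[.data$activity == "discharge"][1]) |>
    dplyr::ungroup() |>
    dplyr::select("case_id", "activity", "day")
  validate_event_log(log)
}

#' Truncate an event log to a follow-up horizon
#'
#' Drops events beyond `horizon` days after discharge; any case left without
#' a terminal event inside the horizon receives an `end_follow_up` event at
#' the horizon boundary, so the truncated log is terminal-complete.
#'
#' @param log Event log (see [validate_event_log()]).
#' @param horizon Horizon in days after discharge (the study views 30 and
#'   90 days).
#' @return Truncated, terminal-complete event log tibble.
#' @export
truncate_to_horizon <- function(log, horizon = 90) {
  log <- validate_event_log(log)
  if (nrow(log) == 0L) return(log)
  stopifnot(is.numeric(horizon), horizon > 0)
  kept <- log[log$day <= horizon, ]
  completed <- kept |>
    dplyr::group_by(.data$case_id) |>
    dplyr::group_modify(function(cs, key) {
      if (!any(cs$activity %in% PM_TERMINAL)) {
        cs <- dplyr::bind_rows(cs, tibble::tibble(activity = "end_follow_up",
                                                  day = horizon))
      }
      cs
    }) |>
    dplyr::ungroup() |>
    dplyr::select("case_id", "activity", "day")
  validate_event_log(completed)
}

#' Directly-follows process map of a care-pathway event log
#'
#' Counts, for every ordered pair of activities, how often one event is
#' directly followed by the other within a case, and the median transition
#' time in days (midpoint convention for even counts). Node counts are the
#' number of visits; for every non-terminal node the outgoing traversals
#' equal the incoming ones (flow conservation), and terminal arrivals sum to
#' the number of cases.
#'
#' @param log A truncated, terminal-complete event log
#'   (see [truncate_to_horizon()]).
#' @return A `process_map`: list with `nodes` (activity, visits, incoming,
#'   outgoing), `edges` (from, to, n, median_days) and `n_cases`. Use
#'   [tidy()] for the edge list, [process_map_text()] for a rendering
#'   description.
#' @export
directly_follows <- function(log) {
  log <- validate_event_log(log)
  if (nrow(log) > 0) {
    incomplete <- log |>
      dplyr::group_by(.data$case_id) |>
      dplyr::summarise(ok = any(.data$activity %in% PM_TERMINAL),
                       .groups = "drop")
    if (!all(incomplete$ok)) {
      abort("Every case must end in a terminal event; run truncate_to_horizon() first.")
    }
  }
  pairs <- log |>
    dplyr::group_by(.data$case_id) |>
    dplyr::mutate(to = dplyr::lead(.data$activity),
                  dt = dplyr::lead(.data$day) - .data$day) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to))
  edges <- pairs |>
    dplyr::group_by(from = .data$activity, to = .data$to) |>
    dplyr::summarise(n = dplyr::n(), median_days = median(.data$dt),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n))
  visits <- log |>
    dplyr::count(activity = .data$activity, name = "visits")
  incoming <- edges |>
    dplyr::group_by(activity = .data$to) |>
    dplyr::summarise(incoming = sum(.data$n), .groups = "drop")
  outgoing <- edges |>
    dplyr::group_by(activity = .data$from) |>
    dplyr::summarise(outgoing = sum(.data$n), .groups = "drop")
  nodes <- visits |>
    dplyr::left_join(incoming, by = "activity") |>
    dplyr::left_join(outgoing, by = "activity") |>
    dplyr::mutate(incoming = dplyr::coalesce(.data$incoming, 0L),
                  outgoing = dplyr::coalesce(.data$outgoing, 0L),
                  terminal = .data$activity %in% PM_TERMINAL)
  structure(list(nodes = nodes, edges = edges,
                 n_cases = length(unique(log$case_id))),
            class = "process_map")
}

#' @export
print.process_map <- function(x, ...) {
  cat("<process_map> ", x$n_cases, " cases, ", nrow(x$edges),
      " directly-follows paths\n", sep = "")
  print(as.data.frame(head(x$edges, 15)), row.names = FALSE)
  if (nrow(x$edges) > 15) cat("  ...\n")
  invisible(x)
}

#' @describeIn directly_follows Edge list as a tibble
#'   (`from`, `to`, `n`, `median_days`).
#' @param x A `process_map`.
#' @param top_k Keep only the `top_k` most frequent paths (default all);
#'   exposed because frequency-filtered "most common pathway" views are the
#'   usual way such maps are drawn.
#' @param ... Unused.
#' @method tidy process_map
#' @export
tidy.process_map <- function(x, top_k = Inf, ...) {
  head(x$edges, n = min(top_k, nrow(x$edges)))
}

#' Graph-description text for a process map
#'
#' DOT (Graphviz) text describing the directly-follows graph, edges
#' annotated with case counts and median transition days; render with any
#' Graphviz tool to obtain a care-pathway diagram.
#'
#' @param map A `process_map`.
#' @param top_k Keep only the `top_k` most frequent paths.
#' @return A character scalar of DOT source.
#' @export
process_map_text <- function(map, top_k = Inf) {
  stopifnot(inherits(map, "process_map"))
  edges <- tidy(map, top_k = top_k)
  lines <- c(
    "digraph care_pathways {",
    "  rankdir=LR;",
    sprintf("  \"%s\" [shape=%s, label=\"%s\\n%d\"];",
            map$nodes$activity,
            ifelse(map$nodes$terminal, "doubleoctagon", "box"),
            map$nodes$activity, map$nodes$visits),
    sprintf("  \"%s\" -> \"%s\" [label=\"%d (%.1f d)\", penwidth=%.2f];",
            edges$from, edges$to, edges$n, edges$median_days,
            0.5 + 4 * edges$n / max(edges$n)),
    "}"
  )
  paste(lines, collapse = "\n")
}

#' @describeIn directly_follows Diagram of the directly-follows graph:
#'   activities as labelled nodes (discharge left, monitoring middle,
#'   terminal events right), arrows weighted by the number of people moving
#'   between events and annotated with median transition days.
#' @param object A `process_map`.
#' @method autoplot process_map
#' @export
autoplot.process_map <- function(object, top_k = Inf, ...) {
  xpos <- c(discharge = 0, gp_monitoring = 1, outpatient_clinic = 1,
            accident_emergency = 1, readmission = 2, death = 2,
            end_follow_up = 2)
  ypos <- c(discharge = 0, gp_monitoring = 1, outpatient_clinic = 0,
            accident_emergency = -1, readmission = 1, death = -1,
            end_follow_up = 0)
  nodes <- dplyr::mutate(object$nodes,
                         x = xpos[.data$activity], y = ypos[.data$activity])
  edges <- tidy(object, top_k = top_k) |>
    dplyr::mutate(x = xpos[.data$from], y = ypos[.data$from],
                  xend = xpos[.data$to], yend = ypos[.data$to])
  ggplot2::ggplot() +
    ggplot2::geom_curve(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$n),
      curvature = 0.15, colour = "steelblue", alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm"))
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y,
                   label = paste0(.data$activity, "\n", .data$visits))
    ) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5), guide = "none") +
    ggplot2::theme_void()
}

#' Unmonitored poor outcomes in an event log
#'
#' A case is an unmonitored poor outcome when its terminal event is a
#' readmission or death with no recorded care contact (GP monitoring,
#' outpatient clinic, or - configurably - accident and emergency) between
#' discharge and that event. Reports the count, the fraction among all
#' poor-outcome cases, and the median days from discharge to the
#' unmonitored outcomes; fractions and medians are `NA` when undefined (no
#' poor outcomes / no unmonitored ones).
#'
#' @param log A truncated, terminal-complete event log.
#' @param include_ae Count accident-and-emergency attendance as an
#'   intervening contact (default `TRUE`)?
#' @return One-row tibble: `n_cases`, `n_poor_outcome`, `n_unmonitored`,
#'   `fraction_unmonitored`, `median_days_to_outcome`.
#' @export
unmonitored_outcomes <- function(log, include_ae = TRUE) {
  log <- validate_event_log(log)
  monitoring <- if (include_ae) PM_MONITORING else
    setdiff(PM_MONITORING, "accident_emergency")
  per_case <- log |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      poor = tail(.data$activity, 1) %in% c("readmission", "death"),
      monitored = any(.data$activity %in% monitoring),
      days = tail(.data$day, 1) - .data$day[1],
      .groups = "drop"
    )
  poor <- per_case[per_case$poor, ]
  unmon <- poor[!poor$monitored, ]
  tibble::tibble(
    n_cases = nrow(per_case),
    n_poor_outcome = nrow(poor),
    n_unmonitored = nrow(unmon),
    fraction_unmonitored = if (nrow(poor)) nrow(unmon) / nrow(poor)
                           else NA_real_,
    median_days_to_outcome = if (nrow(unmon)) median(unmon$days) else NA_real_
  )
}
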