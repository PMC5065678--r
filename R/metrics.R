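#' Compute an alarm-rate report
#'
#' Counts alarm events by the requested grouping and divides by an exposure
#' denominator, so alarm burden can be reported per bed-day, patient-day,
#' hour, or minute and compared across studies. The counting unit is the
#' alarm generation event (one count per `Generated` row), matching how
#' alarm counts appear in the log; pass `unit = "episode"` to count paired
#' episodes instead.
#'
#' The default denominator, bed-days, is inferred from the observed
#' bed-by-calendar-day pairs in the data; this approximates census exposure
#' (an unoccupied but monitored bed contributes nothing, a partially
#' occupied day counts in full) and a user-supplied census can replace it.
#' With MRNs masked to zeros, patient-days coincide with bed-days.
#'
#' @param events Parsed event tibble from [parse_events()], or — with
#'   `unit = "episode"` — the `episodes` tibble from [pair_episodes()].
#' @param grouping Character vector of grouping columns, any of
#'   `"parameter"`, `"priority"` (level + family), `"bed"`,
#'   `"measurement_kind"`, `"audible"`. Empty for a grand total.
#' @param denominator One of `"bed-days"`, `"patient-days"`, `"hours"`,
#'   `"minutes"`, or a positive number supplying the exposure directly (in
#'   which case `denominator_unit` labels it).
#' @param audible_only If `TRUE`, keep only audible alarms: soft INOPs
#'   (level-0 technical alarms) carry no sound and are excluded.
#' @param window Optional POSIXct `c(start, end)` for the time-based
#'   denominators; defaults to the observed timestamp range.
#' @param unit `"event"` (default) or `"episode"`.
#' @param denominator_unit Label used when `denominator` is numeric.
#' @return A `rate_report`: a tibble with the grouping columns, `n`, and
#'   `rate`, with attributes `denominator` (value) and `denominator_unit`.
#' @export
compute_rates <- function(events, grouping = character(),
                          denominator = "bed-days", audible_only = FALSE,
                          window = NULL, unit = c("event", "episode"),
                          denominator_unit = "exposure") {
  unit <- match.arg(unit)
  if (nrow(events) == 0) stop("no events to report on", call. = FALSE)

  if (unit == "event") {
    alarms <- dplyr::filter(
      events,
      .data$event_type %in% c("physiologic", "technical"),
      .data$status == "generated"
    )
    ts <- alarms$timestamp
  } else {
    alarms <- events
    ts <- alarms$start_ts
  }
  alarms$audible <- is_audible(alarms)
  if (audible_only) alarms <- dplyr::filter(alarms, .data$audible)

  bad <- setdiff(grouping, c("parameter", "priority", "bed",
                             "measurement_kind", "audible"))
  if (length(bad) > 0) {
    stop("unknown grouping column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  group_cols <- c(
    if ("parameter" %in% grouping) "parameter",
    if ("priority" %in% grouping) c("priority_family", "priority_level"),
    if ("bed" %in% grouping) "bed_label",
    if ("measurement_kind" %in% grouping) "measurement_kind",
    if ("audible" %in% grouping) "audible"
  )

  denom <- resolve_denominator(events, denominator, window, unit)
  if (denom$value <= 0) {
    stop("rate denominator is zero (no exposure in the data)", call. = FALSE)
  }

  counts <- dplyr::count(alarms, dplyr::across(dplyr::all_of(group_cols)),
                         name = "n")
  counts$rate <- counts$n / denom$value
  structure(counts, class = c("rate_report", class(counts)),
            denominator = denom$value, denominator_unit = denom$unit,
            counting_unit = unit)
}

is_audible <- function(alarms) {
  if ("priority_family" %in% names(alarms)) {
    !(alarms$priority_family %in% "technical" & alarms$priority_level %in% 0L)
  } else {
    rep(TRUE, nrow(alarms))
  }
}

resolve_denominator <- function(events, denominator, window, unit) {
  if (is.numeric(denominator)) {
    stopifnot(length(denominator) == 1)
    return(list(value = denominator, unit = "exposure"))
  }
  ts <- if (unit == "episode") events$start_ts else events$timestamp
  if (is.null(window)) window <- range(ts, na.rm = TRUE)
  switch(
    denominator,
    "bed-days" = ,
    "patient-days" = {
      days <- dplyr::n_distinct(paste(events$bed_label,
                                      format(ts, "%Y-%m-%d", tz = "UTC")))
      list(value = days, unit = denominator)
    },
    "hours" = list(value = as.numeric(difftime(window[2], window[1],
                                               units = "hours")),
                   unit = "hours"),
    "minutes" = list(value = as.numeric(difftime(window[2], window[1],
                                                 units = "mins")),
                     unit = "minutes"),
    stop("unknown denominator: ", denominator, call. = FALSE)
  )
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("Alarm rate report (per %s; denominator = %s %s; unit = %s)\n",
              attr(x, "denominator_unit"),
              format(attr(x, "denominator")), attr(x, "denominator_unit"),
              attr(x, "counting_unit")))
  NextMethod()
  invisible(x)
}

#' Summarize clinician actions
#'
#' Tallies user-action events by action kind. Silence, Pause All Alarms and
#' Resume All Alarms are reported as separate kinds, never pooled.
#'
#' @param events Parsed event tibble from [parse_events()].
#' @return Tibble with `action_kind` and `n`, sorted by descending count;
#'   zero rows when the log holds no actions.
#' @export
summarize_actions <- function(events) {
  acts <- dplyr::filter(events, .data$event_type == "action")
  if (nrow(acts) == 0) {
    return(tibble::tibble(action_kind = character(), n = integer()))
  }
  dplyr::arrange(dplyr::count(acts, .data$action_kind, name = "n"),
                 dplyr::desc(.data$n), .data$action_kind)
}

#' Compare alarm rates before and after an intervention
#'
#' Splits the event stream at `boundary_ts`, computes a rate report on each
#' side with the same grouping and denominator definition, and reports
#' per-group absolute and percent change — the standard pre/post evaluation
#' of an alarm-parameter intervention.
#'
#' @param events Parsed event tibble.
#' @param boundary_ts POSIXct split point: events strictly before fall in
#'   the pre period, at or after in the post period.
#' @param grouping,denominator,audible_only Passed to [compute_rates()].
#' @return A `period_comparison` list: `pre` and `post` rate reports (or
#'   `NULL` for an empty side, which is flagged in `empty_side`), and
#'   `deltas`, a tibble with per-group `rate_pre`, `rate_post`,
#'   `delta_abs`, `delta_pct`.
#' @export
compare_periods <- function(events, boundary_ts, grouping = character(),
                            denominator = "bed-days", audible_only = FALSE) {
  pre_ev <- dplyr::filter(events, .data$timestamp < boundary_ts)
  post_ev <- dplyr::filter(events, .data$timestamp >= boundary_ts)
  empty_side <- c(if (nrow(pre_ev) == 0) "pre", if (nrow(post_ev) == 0) "post")

  mk <- function(ev) {
    if (nrow(ev) == 0) return(NULL)
    compute_rates(ev, grouping = grouping, denominator = denominator,
                  audible_only = audible_only)
  }
  pre <- mk(pre_ev)
  post <- mk(post_ev)

  deltas <- NULL
  if (!is.null(pre) && !is.null(post)) {
    keys <- setdiff(names(pre), c("n", "rate"))
    pre_t <- dplyr::rename(tibble::as_tibble(pre), n_pre = "n", rate_pre = "rate")
    post_t <- dplyr::rename(tibble::as_tibble(post), n_post = "n",
                            rate_post = "rate")
    deltas <- if (length(keys) == 0) {
      dplyr::bind_cols(pre_t, post_t) # ungrouped: single grand-total row each
    } else {
      dplyr::full_join(pre_t, post_t, by = keys)
    }
    deltas$delta_abs <- deltas$rate_post - deltas$rate_pre
    deltas$delta_pct <- 100 * deltas$delta_abs / deltas$rate_pre
  }
  structure(list(pre = pre, post = post, deltas = deltas,
                 empty_side = empty_side, boundary_ts = boundary_ts),
            class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat("Pre/post comparison at", format(x$boundary_ts, tz = "UTC"), "\n")
  if (length(x$empty_side) > 0) {
    cat("NOTE: empty side(s):", paste(x$empty_side, collapse = ", "),
        "- rates absent, not zero\n")
  }
  if (!is.null(x$deltas)) print(x$deltas)
  invisible(x)
}
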