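#' Scan programmed alarm limits against a safe-range policy
#'
#' Harvests every programmed limit visible in the log — the limit field of
#' numerical alarm messages (a `<` comparison reveals a lower limit, `>` an
#' upper limit) and the bounds of Alarm Limit Change actions — and reports
#' the observed minimum and maximum per parameter and side. When a
#' safe-range policy is supplied, each distinct (bed, parameter, limit)
#' outside its allowed interval becomes a finding citing its source rows.
#'
#' No safe ranges are built in: what counts as unsafe (for example, a Desat
#' lower limit of 50%) is clinical policy, so the policy always comes from
#' the caller or a config file.
#'
#' @param events Parsed event tibble from [parse_events()].
#' @param spec Optional safe-range policy: a tibble with columns
#'   `parameter`, `side` (`"lower"`/`"upper"`), `allowed_min`,
#'   `allowed_max`.
#' @return A list with `observed` (tibble: `parameter`, `side`, `min_limit`,
#'   `max_limit`, `n`), `findings` (tibble of unsafe settings: `kind`,
#'   `bed_label`, `parameter`, `side`, `observed`, `allowed_min`,
#'   `allowed_max`, `source_rows`), and `unchecked` (parameters seen in the
#'   log but absent from the policy).
#' @export
#' @examples
#' path <- system.file("extdata", "desat_limit_examples.csv", package = "alarmaudit")
#' ev <- parse_events(read_audit_log(path))
#' scan_limit_settings(ev)$observed
scan_limit_settings <- function(events, spec = NULL) {
  harvested <- harvest_limits(events)
  if (nrow(harvested) == 0) {
    observed <- tibble::tibble(parameter = character(), side = character(),
                               min_limit = double(), max_limit = double(),
                               n = integer())
    return(list(observed = observed, findings = empty_findings(),
                unchecked = character()))
  }
  observed <- dplyr::summarise(
    dplyr::group_by(harvested, .data$parameter, .data$side),
    min_limit = min(.data$limit), max_limit = max(.data$limit),
    n = dplyr::n(), .groups = "drop"
  )

  findings <- empty_findings()
  unchecked <- character()
  if (!is.null(spec)) {
    spec <- tibble::as_tibble(spec)
    stopifnot(all(c("parameter", "side", "allowed_min", "allowed_max")
                  %in% names(spec)),
              !anyDuplicated(paste(spec$parameter, spec$side)),
              all(spec$allowed_min <= spec$allowed_max))
    unchecked <- sort(setdiff(unique(harvested$parameter), spec$parameter))
    joined <- dplyr::inner_join(harvested, spec, by = c("parameter", "side"))
    bad <- dplyr::filter(joined, .data$limit < .data$allowed_min |
                           .data$limit > .data$allowed_max)
    if (nrow(bad) > 0) {
      findings <- dplyr::summarise(
        dplyr::group_by(bad, .data$bed_label, .data$parameter, .data$side,
                        observed = .data$limit,
                        .data$allowed_min, .data$allowed_max),
        source_rows = list(sort(unique(.data$row_index))), .groups = "drop"
      )
      findings <- dplyr::mutate(findings, kind = "unsafe_limit",
                                .before = 1)
      findings <- dplyr::arrange(findings, .data$parameter, .data$bed_label,
                                 .data$observed)
    }
  }
  list(observed = observed, findings = findings, unchecked = unchecked)
}

harvest_limits <- function(events) {
  num <- dplyr::filter(events, .data$event_type == "physiologic",
                       .data$measurement_kind == "numerical",
                       !is.na(.data$limit))
  from_alarms <- tibble::tibble(
    bed_label = num$bed_label,
    parameter = num$parameter,
    side = as.character(ifelse(num$direction == "below", "lower", "upper")),
    limit = num$limit,
    row_index = num$row_index
  )
  lc <- dplyr::filter(events, .data$event_type == "action",
                      .data$action_kind %in% "Alarm Limit Change")
  from_actions <- dplyr::bind_rows(
    tibble::tibble(bed_label = lc$bed_label, parameter = lc$limit_param,
                   side = "lower", limit = lc$limit_low,
                   row_index = lc$row_index),
    tibble::tibble(bed_label = lc$bed_label, parameter = lc$limit_param,
                   side = "upper", limit = lc$limit_high,
                   row_index = lc$row_index)
  )
  out <- dplyr::bind_rows(from_alarms, from_actions)
  dplyr::filter(out, !is.na(.data$limit))
}

empty_findings <- function() {
  tibble::tibble(kind = character(), bed_label = character(),
                 parameter = character(), side = character(),
                 observed = double(), allowed_min = double(),
                 allowed_max = double(), source_rows = list())
}

#' Detect inconsistent alarm priorities
#'
#' The same alarm condition should carry the same priority everywhere on a
#' unit, yet logs show e.g. `*HR 153>150` on one monitor and
#' `**HR 153 >150` on another. For physiologic alarms the condition
#' signature is (parameter, direction, limit) — the triggering value and
#' limit are held fixed while the star count differs; for technical alarms
#' the signature is the INOP name alone. One finding is emitted per
#' signature exhibiting two or more distinct priority levels, listing all
#' levels, observed trigger values and source rows.
#'
#' @param events Parsed event tibble from [parse_events()].
#' @return Tibble of findings: `kind`, `parameter`, `direction`, `limit`,
#'   `levels` (list of sorted distinct levels), `trigger_value` (the common
#'   trigger value when unique, else `NA`), `trigger_values` (list),
#'   `source_rows` (list).
#' @export
check_priority_consistency <- function(events) {
  alarms <- dplyr::filter(events,
                          .data$event_type %in% c("physiologic", "technical"),
                          !is.na(.data$priority_level))
  if (nrow(alarms) == 0) return(empty_priority_findings())

  sig <- dplyr::mutate(
    alarms,
    sig_direction = ifelse(.data$priority_family == "technical",
                           NA_character_, .data$direction),
    sig_limit = ifelse(.data$priority_family == "technical",
                       NA_real_, .data$limit)
  )
  grouped <- dplyr::group_by(sig, .data$priority_family, .data$parameter,
                             .data$sig_direction, .data$sig_limit)
  out <- dplyr::summarise(
    grouped,
    levels = list(sort(unique(.data$priority_level))),
    trigger_values = list(sort(unique(.data$value[!is.na(.data$value)]))),
    source_rows = list(sort(unique(.data$row_index))),
    .groups = "drop"
  )
  out <- dplyr::filter(out, lengths(.data$levels) >= 2)
  if (nrow(out) == 0) return(empty_priority_findings())
  tibble::tibble(
    kind = "priority_inconsistency",
    parameter = out$parameter,
    direction = out$sig_direction,
    limit = out$sig_limit,
    levels = out$levels,
    trigger_value = vapply(out$trigger_values, function(v) {
      if (length(v) == 1) v else NA_real_
    }, double(1)),
    trigger_values = out$trigger_values,
    source_rows = out$source_rows
  )
}

empty_priority_findings <- function() {
  tibble::tibble(kind = character(), parameter = character(),
                 direction = character(), limit = double(), levels = list(),
                 trigger_value = double(), trigger_values = list(),
                 source_rows = list())
}

#' Check unit-configuration compliance
#'
#' After a unit-wide settings change (for example "Paired PVCs alarms
#' disabled"), monitors missed by the rollout betray themselves in the log:
#' an alarm of a supposedly disabled type is direct evidence of
#' non-compliance, and the log names the bed. Occurrence of a disabled
#' alarm after the expectation's effective date is the primary evidence;
#' optionally, absence of the corresponding Alarm Off action can be
#' required as secondary evidence.
#'
#' @param events Parsed event tibble from [parse_events()].
#' @param expectation Tibble with columns `parameter` (must exist in the
#'   registry), `rule` (currently `"disabled"`), and optional
#'   `effective_ts` (POSIXct; default: beginning of the log).
#' @param registry Registry list; expectation parameters are validated
#'   against it.
#' @param require_action If `TRUE`, beds with no logged `Alarm Off` action
#'   for the parameter are also flagged even without an alarm occurrence.
#' @return Tibble of findings: `kind`, `bed_label`, `parameter`,
#'   `evidence` (`"alarm_occurred"` or `"action_absent"`), `source_rows`.
#' @export
check_unit_compliance <- function(events, expectation,
                                  registry = default_registry(),
                                  require_action = FALSE) {
  expectation <- tibble::as_tibble(expectation)
  stopifnot(all(c("parameter", "rule") %in% names(expectation)))
  unknown <- setdiff(expectation$parameter, registry$parameters)
  if (length(unknown) > 0) {
    stop("expectation references parameter(s) not in the registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!"effective_ts" %in% names(expectation)) {
    expectation$effective_ts <- min(events$timestamp)
  }

  findings <- list()
  for (i in seq_len(nrow(expectation))) {
    par <- expectation$parameter[i]
    eff <- expectation$effective_ts[i]
    hits <- dplyr::filter(events,
                          .data$event_type %in% c("physiologic", "technical"),
                          .data$parameter == par,
                          .data$status == "generated",
                          .data$timestamp >= eff)
    if (nrow(hits) > 0) {
      by_bed <- dplyr::summarise(dplyr::group_by(hits, .data$bed_label),
                                 source_rows = list(sort(.data$row_index)),
                                 .groups = "drop")
      findings[[length(findings) + 1]] <- tibble::tibble(
        kind = "noncompliant_bed", bed_label = by_bed$bed_label,
        parameter = par, evidence = "alarm_occurred",
        source_rows = by_bed$source_rows)
    }
    if (require_action) {
      off <- dplyr::filter(events, .data$event_type == "action",
                           .data$action_kind %in% "Alarm Off",
                           .data$action_detail %in% par)
      silent_beds <- setdiff(unique(events$bed_label), unique(off$bed_label))
      flagged <- if (length(findings) > 0) {
        unique(dplyr::bind_rows(findings)$bed_label)
      } else character()
      silent_beds <- setdiff(silent_beds, flagged)
      if (length(silent_beds) > 0) {
        findings[[length(findings) + 1]] <- tibble::tibble(
          kind = "noncompliant_bed", bed_label = silent_beds,
          parameter = par, evidence = "action_absent",
          source_rows = list(integer()))
      }
    }
  }
  if (length(findings) == 0) {
    return(tibble::tibble(kind = character(), bed_label = character(),
                          parameter = character(), evidence = character(),
                          source_rows = list()))
  }
  dplyr::arrange(dplyr::bind_rows(findings), .data$parameter, .data$bed_label)
}

#' Plan audit-log retrievals under retention and window limits
#'
#' The central station stores the audit log for 90 days before overwriting
#' the oldest data, and one retrieval covers at most 50 days and at least
#' 15 minutes. A span is covered greedily with 50-day windows plus a
#' remainder, so 90 days needs 2 retrievals (50 + 40) and a 140-day
#' (20-week) project needs 3 (50 + 50 + 40) — the latter is infeasible as a
#' single retrospective pull and must be scheduled prospectively.
#'
#' @param span_days Span to cover, in days (fractions allowed down to the
#'   15-minute minimum).
#' @return A `retrieval_plan` list: `span_days`, `windows` (day lengths
#'   summing to the span, each within \[15 min, 50 days\]), `n_retrievals`,
#'   and `retention_feasible` (`FALSE` when the span exceeds the 90-day
#'   storage period).
#' @export
#' @examples
#' plan_retrievals(90)   # 2 windows: 50 + 40
#' plan_retrievals(140)  # 3 windows, flagged as needing prospective pulls
plan_retrievals <- function(span_days) {
  stopifnot(is.numeric(span_days), length(span_days) == 1)
  min_days <- 15 / (24 * 60)
  if (span_days < min_days) {
    stop("retrieval span must be at least 15 minutes (",
         format(min_days, digits = 4), " days)", call. = FALSE)
  }
  n_full <- floor(span_days / 50)
  rem <- span_days - 50 * n_full
  windows <- c(rep(50, n_full), if (rem > 0) rem)
  # a remainder below the 15-minute floor folds into the last full window
  if (rem > 0 && rem < min_days && n_full > 0) {
    windows <- c(rep(50, n_full - 1), 50 + rem)
  }
  structure(
    list(span_days = span_days, windows = windows,
         n_retrievals = length(windows),
         retention_feasible = span_days <= 90),
    class = "retrieval_plan"
  )
}

#' @export
print.retrieval_plan <- function(x, ...) {
  cat(sprintf("%d window%s: %s (span %s days)\n", x$n_retrievals,
              if (x$n_retrievals == 1) "" else "s",
              paste(format(x$windows, trim = TRUE), collapse = " + "),
              format(x$span_days)))
  if (!x$retention_feasible) {
    cat("span exceeds the 90-day storage period:",
        "not retrievable retrospectively in one pass;",
        "schedule prospective pulls\n")
  }
  invisible(x)
}
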