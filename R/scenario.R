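#' Run a timed announcement scenario
#'
#' Replays a scenario of alarm onsets, condition ends and clinician actions
#' through the announcement simulator, recording the announcement after
#' every step and emitting an audit-log-format event stream that
#' [read_audit_log()]/[parse_events()] can consume.
#'
#' @param scenario Tibble (or CSV path) with columns `timestamp`, `kind`
#'   (`"onset"`, `"end"`, `"action"`), `parameter`, `priority_level`,
#'   `priority_family` (default physiologic), `action` (for action rows:
#'   Silence/Pause/Resume), `duration_s` (pause length, `Inf` allowed),
#'   `bed_label` (optional, default `"9115-S1"`).
#' @param registry Registry list for chain/latching/yellow-class lookups.
#' @param yellow_pause_only Site pause configuration (see
#'   [monitor_state()]).
#' @return A list: `trace` (tibble with one row per step: `timestamp`,
#'   `step_kind`, `announced`, `audible`, `n_displayed`, `n_suppressed`)
#'   and `records` (audit-record tibble of the emitted event stream).
#' @export
run_scenario <- function(scenario, registry = default_registry(),
                         yellow_pause_only = FALSE) {
  if (is.character(scenario)) {
    scenario <- readr::read_csv(scenario, show_col_types = FALSE,
                                progress = FALSE)
  }
  scenario <- tibble::as_tibble(scenario)
  stopifnot(all(c("timestamp", "kind") %in% names(scenario)))
  if (!"priority_family" %in% names(scenario)) {
    scenario$priority_family <- "physiologic"
  }
  if (!"bed_label" %in% names(scenario)) scenario$bed_label <- "9115-S1"
  scenario$timestamp <- parse_log_timestamp(scenario$timestamp)
  scenario <- scenario[order(scenario$timestamp), ]

  state <- monitor_state(active_alarms(character(), integer(),
                                       registry = registry),
                         yellow_pause_only = yellow_pause_only)
  next_id <- 1L
  open_ids <- list() # parameter -> alarm_id
  trace <- list()
  recs <- list()
  emit_rec <- function(ts, bed, msg) {
    recs[[length(recs) + 1]] <<- tibble::tibble(
      timestamp = ts, bed_label = bed, mrn = "0000000", raw_message = msg,
      device_name = "SIM")
  }

  for (i in seq_len(nrow(scenario))) {
    row <- scenario[i, ]
    if (row$kind == "onset") {
      al <- active_alarms(row$parameter, row$priority_level,
                          row$priority_family, onset_ts = row$timestamp,
                          registry = registry)
      al$alarm_id <- next_id
      open_ids[[row$parameter]] <- next_id
      next_id <- next_id + 1L
      state$active <- dplyr::bind_rows(state$active, al)
      mark <- if (row$priority_family == "physiologic") {
        strrep("*", row$priority_level)
      } else strrep("!", max(0L, row$priority_level))
      emit_rec(row$timestamp, row$bed_label,
               sprintf("%s%s Generated.", mark, row$parameter))
    } else if (row$kind == "end") {
      id <- open_ids[[row$parameter]]
      if (!is.null(id)) {
        state <- end_condition(state, id)
        open_ids[[row$parameter]] <- NULL
      }
      mark <- if (row$priority_family == "physiologic") {
        strrep("*", row$priority_level)
      } else strrep("!", max(0L, row$priority_level))
      emit_rec(row$timestamp, row$bed_label,
               sprintf("%s%s Ended.", mark, row$parameter))
    } else if (row$kind == "action") {
      dur <- if ("duration_s" %in% names(row) && !is.na(row$duration_s)) {
        row$duration_s
      } else 120
      state <- apply_user_action(state, row$action, now = row$timestamp,
                                 duration_s = dur)
      msg <- switch(row$action, Silence = "Silence.",
                    Pause = "Pause All Alarms.",
                    Resume = "Resume All Alarms.")
      emit_rec(row$timestamp, row$bed_label, msg)
    } else {
      stop("unknown scenario step kind: ", row$kind, call. = FALSE)
    }
    res <- state_announce(state, now = row$timestamp)
    trace[[length(trace) + 1]] <- tibble::tibble(
      timestamp = row$timestamp,
      step_kind = row$kind,
      announced = if (nrow(res$announced) > 0) res$announced$parameter
                  else NA_character_,
      audible = if (nrow(res$announced) > 0) res$announced$audible else FALSE,
      n_displayed = nrow(res$display_list),
      n_suppressed = nrow(res$suppressed))
  }

  records <- dplyr::bind_rows(recs)
  if (nrow(records) > 0) records$row_index <- seq_len(nrow(records))
  list(trace = dplyr::bind_rows(trace), records = records,
       final_state = state)
}
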