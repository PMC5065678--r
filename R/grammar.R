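#' Parse "Alarm and Action" message text
#'
#' Implements the message grammar of the central-station audit log. Each
#' message is classified as exactly one of:
#'
#' * **physiologic alarm** — leading asterisks give the priority (1 `*`
#'   advisory, 2 `**` yellow/moderate, 3 `***` red/high). Numerical alarms
#'   carry the triggering value, the programmed limit and the crossing
#'   direction (`"**PAPd 18 >16 Generated."` reads as value 18 above limit
#'   16); whitespace around the comparator is optional (`153>150` and
#'   `153 >150` both occur). Categorical alarms (arrhythmia classes such as
#'   Multiform PVCs) carry none of the three. Apnea has three printed
#'   forms: plain `***Apnea` (categorical), `***Apnea X:YY` (duration
#'   `60*X + YY` seconds in `apnea_seconds`), and `***Apnea > 20 sec`
#'   (`apnea_gt20` flag).
#' * **technical (INOP) alarm** — leading exclamation marks give the
#'   priority (`!!` moderate, `!!!` high); INOP names with no mark (e.g.
#'   `"ECG Leads Off Generated."`) are soft INOPs at level 0, which carry
#'   no sound.
#' * **sound event** — `"Red alarm sound played."`, `"Yellow alarm sound
#'   played."`, `"INOP sound played."`.
#' * **user action** — clinician interaction (Silence, Pause/Resume All
#'   Alarms, transfers, measurement and alarm toggles, alarm-limit
#'   changes). Limit-change messages yield the parameter and new bound(s)
#'   with sign preserved.
#'
#' The trailing `Generated`/`Ended` status is matched case-insensitively
#' (the device prints both `Ended` and `ended`). A message matching no rule
#' is returned as an `unparsed` event carrying the raw text — never
#' silently dropped.
#'
#' @param x Character vector of message texts (normalized or raw; raw text
#'   is cleaned with [normalize_message_text()] first).
#' @return A tibble with one row per message and columns `raw_message`,
#'   `event_type` (`physiologic`/`technical`/`sound`/`action`/`unparsed`),
#'   `priority_level`, `priority_family`, `color`, `parameter`,
#'   `measurement_kind`, `value`, `limit`, `direction`, `status`,
#'   `apnea_seconds`, `apnea_gt20`, `sound_kind`, `action_kind`,
#'   `action_detail`, `limit_param`, `limit_low`, `limit_high`.
#' @export
#' @examples
#' parse_messages(c("**PAPd 18 >16 Generated.", "Silence.",
#'                  "ECG Leads Off Generated."))
parse_messages <- function(x) {
  x <- normalize_message_text(as.character(x))
  rows <- lapply(x, parse_one_message)
  tibble::tibble(
    raw_message = x,
    event_type = vapply(rows, `[[`, character(1), "event_type"),
    priority_level = vapply(rows, `[[`, integer(1), "priority_level"),
    priority_family = vapply(rows, `[[`, character(1), "priority_family"),
    color = vapply(rows, `[[`, character(1), "color"),
    parameter = vapply(rows, `[[`, character(1), "parameter"),
    measurement_kind = vapply(rows, `[[`, character(1), "measurement_kind"),
    value = vapply(rows, `[[`, double(1), "value"),
    limit = vapply(rows, `[[`, double(1), "limit"),
    direction = vapply(rows, `[[`, character(1), "direction"),
    status = vapply(rows, `[[`, character(1), "status"),
    apnea_seconds = vapply(rows, `[[`, double(1), "apnea_seconds"),
    apnea_gt20 = vapply(rows, `[[`, logical(1), "apnea_gt20"),
    sound_kind = vapply(rows, `[[`, character(1), "sound_kind"),
    action_kind = vapply(rows, `[[`, character(1), "action_kind"),
    action_detail = vapply(rows, `[[`, character(1), "action_detail"),
    limit_param = vapply(rows, `[[`, character(1), "limit_param"),
    limit_low = vapply(rows, `[[`, double(1), "limit_low"),
    limit_high = vapply(rows, `[[`, double(1), "limit_high")
  )
}

#' Parse a single message
#'
#' @param x One message text.
#' @return A one-row tibble; see [parse_messages()].
#' @export
parse_message <- function(x) {
  stopifnot(length(x) == 1, !is.na(x), nchar(stringr::str_trim(x)) > 0)
  parse_messages(x)
}

# schema template for one parsed message
blank_event <- function() {
  list(
    event_type = "unparsed", priority_level = NA_integer_,
    priority_family = NA_character_, color = NA_character_,
    parameter = NA_character_, measurement_kind = NA_character_,
    value = NA_real_, limit = NA_real_, direction = NA_character_,
    status = NA_character_, apnea_seconds = NA_real_, apnea_gt20 = NA,
    sound_kind = NA_character_, action_kind = NA_character_,
    action_detail = NA_character_, limit_param = NA_character_,
    limit_low = NA_real_, limit_high = NA_real_
  )
}

NUM_RE <- "-?\\d+(?:\\.\\d+)?"

parse_one_message <- function(msg) {
  ev <- blank_event()
  if (is.na(msg) || nchar(msg) == 0) return(ev)

  # sound events
  m <- stringr::str_match(msg, "^(Red|Yellow) alarm sound played\\.?$")
  if (!is.na(m[1])) {
    ev$event_type <- "sound"; ev$sound_kind <- tolower(m[2]); return(ev)
  }
  if (grepl("^INOP sound played\\.?$", msg)) {
    ev$event_type <- "sound"; ev$sound_kind <- "inop"; return(ev)
  }

  marks <- stringr::str_match(msg, "^(\\*{1,3}|!{1,3})\\s*(.*)$")
  stars <- 0L; bangs <- 0L
  body <- msg
  if (!is.na(marks[1])) {
    if (startsWith(marks[2], "*")) stars <- nchar(marks[2]) else bangs <- nchar(marks[2])
    body <- marks[3]
  }

  status <- NA_character_
  sm <- stringr::str_match(body, stringr::regex("^(.*?)\\s*(Generated|Ended)\\.?$",
                                                ignore_case = TRUE))
  if (!is.na(sm[1])) {
    status <- tolower(sm[3])
    body <- sm[2]
  }
  body <- stringr::str_remove(stringr::str_trim(body), "\\.$")

  if (stars > 0) {
    return(parse_physiologic(ev, body, stars, status))
  }
  if (bangs > 0) {
    ev$event_type <- "technical"
    ev$priority_family <- "technical"
    ev$priority_level <- as.integer(bangs)
    ev$color <- "none"
    ev$parameter <- body
    ev$measurement_kind <- "categorical"
    ev$status <- if (is.na(status)) "generated" else status
    return(ev)
  }
  if (!is.na(status)) {
    # statused message with no priority mark: soft INOP
    ev$event_type <- "technical"
    ev$priority_family <- "technical"
    ev$priority_level <- 0L
    ev$color <- "none"
    ev$parameter <- body
    ev$measurement_kind <- "categorical"
    ev$status <- status
    return(ev)
  }
  parse_action(ev, body)
}

parse_physiologic <- function(ev, body, stars, status) {
  ev$event_type <- "physiologic"
  ev$priority_family <- "physiologic"
  ev$priority_level <- as.integer(stars)
  ev$color <- c("advisory", "yellow", "red")[stars]
  ev$status <- if (is.na(status)) "generated" else status

  # Apnea's three display forms come before the generic numeric pattern so
  # that "> 20 sec" is not read as a limit comparison
  am <- stringr::str_match(body, "^Apnea (\\d+):(\\d{2})$")
  if (!is.na(am[1])) {
    ev$parameter <- "Apnea"
    ev$measurement_kind <- "numerical"
    ev$apnea_seconds <- 60 * as.numeric(am[2]) + as.numeric(am[3])
    return(ev)
  }
  if (grepl("^Apnea\\s*>\\s*20 sec$", body)) {
    ev$parameter <- "Apnea"
    ev$measurement_kind <- "numerical"
    ev$apnea_gt20 <- TRUE
    return(ev)
  }

  nm <- stringr::str_match(
    body, paste0("^(.+?)\\s+(", NUM_RE, ")\\s*([<>])\\s*(", NUM_RE, ")$"))
  if (!is.na(nm[1])) {
    ev$parameter <- nm[2]
    ev$measurement_kind <- "numerical"
    ev$value <- as.numeric(nm[3])
    ev$limit <- as.numeric(nm[5])
    ev$direction <- if (nm[4] == ">") "above" else "below"
    return(ev)
  }
  ev$parameter <- body
  ev$measurement_kind <- "categorical"
  ev$direction <- "none"
  ev
}

parse_action <- function(ev, body) {
  ev$event_type <- "action"
  set <- function(kind, detail = NA_character_) {
    ev$action_kind <- kind; ev$action_detail <- detail; ev
  }
  if (grepl("^Silence$", body, ignore.case = TRUE)) return(set("Silence"))
  if (grepl("^Pause All Alarms$", body, ignore.case = TRUE)) return(set("Pause All Alarms"))
  if (grepl("^Resume All Alarms$", body, ignore.case = TRUE)) return(set("Resume All Alarms"))

  m <- stringr::str_match(body, "^Patient transferred to (.+)$")
  if (!is.na(m[1])) return(set("Transfer", m[2]))
  m <- stringr::str_match(body, "^Patient category set to (.+)$")
  if (!is.na(m[1])) return(set("Patient Category Changed", m[2]))
  m <- stringr::str_match(body, "^Pacer algorithm set to (.+)$")
  if (!is.na(m[1])) return(set("Paced Status Changed", m[2]))
  if (grepl("^Equipment Offline$", body)) return(set("Equipment Offline"))
  if (grepl("^Equipment Online$", body)) return(set("Equipment Online"))
  m <- stringr::str_match(body, "^Stand ?By (On|Off)$")
  if (!is.na(m[1])) return(set(paste("Stand By", m[2])))

  lc <- parse_limit_change_body(ev, body)
  if (!is.null(lc)) return(lc)

  # "Arrhy: Missed Beat Off." toggles an alarm class; a bare
  # "<measurement> Off." toggles the measurement itself
  m <- stringr::str_match(body, "^Arrhy: (.+?) (On|Off)$")
  if (!is.na(m[1])) return(set(paste("Alarm", m[3]), m[2]))
  m <- stringr::str_match(body, "^(.+?) (On|Off)$")
  if (!is.na(m[1])) return(set(paste("Measurement", m[3]), m[2]))

  ev$event_type <- "unparsed"
  ev$action_kind <- NA_character_
  ev
}

#' Parse an alarm-limit-change action message
#'
#' Settings messages take two forms: a single-bound form such as
#' `"SpO2: Desat Limit 78."` and a paired high/low form such as
#' `"ST: Al. Limits ST-V2 High: 1.6 ST-V2 Low: -1.6."` (the Unicode minus
#' the export prints is normalized to ASCII before matching, so signs are
#' preserved). A settings-shaped message with no numeric bound — e.g.
#' `"Arrhy: Missed Beat Off."` — is not a limit change; it parses as an
#' Alarm On/Off action via [parse_messages()].
#'
#' Single-bound messages are recorded as lower limits: the only
#' single-bound form the export prints (Desat) programs a lower limit.
#'
#' @param x One message text.
#' @return A one-row tibble (see [parse_messages()]) with `action_kind`
#'   `"Alarm Limit Change"` and `limit_param`, `limit_low`, `limit_high`
#'   filled in; an `unparsed` row if the message is not a limit change.
#' @export
#' @examples
#' parse_limit_change("SpO2: Desat Limit 78.")
parse_limit_change <- function(x) {
  out <- parse_message(x)
  if (!identical(out$action_kind, "Alarm Limit Change")) {
    out$event_type <- "unparsed"
  }
  out
}

parse_limit_change_body <- function(ev, body) {
  # paired form: "<src>: Al. Limits <param> High: <v> <param> Low: <v>"
  m <- stringr::str_match(
    body, paste0("^([^:]+): Al\\. Limits (\\S+) High: (", NUM_RE,
                 ")\\s+\\S+ Low: (", NUM_RE, ")$"))
  if (!is.na(m[1])) {
    ev$event_type <- "action"
    ev$action_kind <- "Alarm Limit Change"
    ev$action_detail <- body
    ev$limit_param <- m[3]
    ev$limit_high <- as.numeric(m[4])
    ev$limit_low <- as.numeric(m[5])
    return(ev)
  }
  # single-bound form: "<src>: <param> Limit <v>"
  m <- stringr::str_match(body, paste0("^([^:]+): (.+?) Limit (", NUM_RE, ")$"))
  if (!is.na(m[1])) {
    ev$event_type <- "action"
    ev$action_kind <- "Alarm Limit Change"
    ev$action_detail <- body
    ev$limit_param <- m[3]
    ev$limit_low <- as.numeric(m[4])
    return(ev)
  }
  NULL
}

#' Parse the messages of an audit-record tibble
#'
#' Binds the record columns of [read_audit_log()] output with the parsed
#' message columns of [parse_messages()], giving the event table the
#' episode, metrics, and audit functions consume.
#'
#' @param records Tibble from [read_audit_log()].
#' @return Tibble of events: the record columns plus the parsed columns.
#' @export
parse_events <- function(records) {
  parsed <- parse_messages(records$raw_message)
  dplyr::bind_cols(
    records[, c("timestamp", "bed_label", "mrn", "device_name", "row_index")],
    parsed
  )
}

#' Render a parsed physiologic or technical alarm back to message text
#'
#' Inverse of the alarm grammar: the priority marks, parameter, value/limit
#' fields and status are reassembled, so the star (or exclamation-mark)
#' count of a parsed alarm always reproduces the original.
#'
#' @param event One-row tibble of a parsed alarm event.
#' @return Message text.
#' @export
format_alarm <- function(event) {
  stopifnot(nrow(event) == 1, event$event_type %in% c("physiologic", "technical"))
  mark <- if (event$priority_family == "physiologic") {
    strrep("*", event$priority_level)
  } else {
    strrep("!", event$priority_level)
  }
  stat <- paste0(toupper(substring(event$status, 1, 1)), substring(event$status, 2))
  core <- if (identical(event$measurement_kind, "numerical") &&
              !is.na(event$value)) {
    cmp <- if (event$direction == "above") ">" else "<"
    paste0(event$parameter, " ", format_num(event$value), " ", cmp,
           format_num(event$limit))
  } else if (!is.na(event$apnea_seconds)) {
    sprintf("Apnea %d:%02d", as.integer(event$apnea_seconds) %/% 60L,
            as.integer(event$apnea_seconds) %% 60L)
  } else if (isTRUE(event$apnea_gt20)) {
    "Apnea > 20 sec"
  } else {
    event$parameter
  }
  paste0(mark, core, " ", stat, ".")
}

format_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}
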