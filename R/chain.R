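#' Build an active-alarm table for the announcement simulator
#'
#' @param parameter Character vector of alarming parameter names.
#' @param priority_level Integer priorities (physiologic 1--3; technical
#'   0, 2, 3).
#' @param priority_family `"physiologic"` or `"technical"` per alarm.
#' @param onset_ts POSIXct onset times.
#' @param acknowledged Has the alarm been silenced/acknowledged?
#' @param condition_active Is the triggering condition still present?
#' @param registry Registry supplying chain membership, latching and
#'   yellow-length classes.
#' @return Tibble of active alarms with derived columns `chain` (pvc /
#'   beat_detection / rate / none), `latching` (level-3 physiologic alarms
#'   in the latching set), and `yellow_class` (`"long"`/`"short"` for
#'   yellow alarms).
#' @export
active_alarms <- function(parameter, priority_level,
                          priority_family = "physiologic",
                          onset_ts = Sys.time(), acknowledged = FALSE,
                          condition_active = TRUE,
                          registry = default_registry()) {
  n <- length(parameter)
  out <- tibble::tibble(
    alarm_id = seq_len(n),
    parameter = parameter,
    priority_level = as.integer(rep_len(priority_level, n)),
    priority_family = rep_len(priority_family, n),
    onset_ts = rep(as.POSIXct(onset_ts, tz = "UTC"), length.out = n),
    acknowledged = rep_len(acknowledged, n),
    condition_active = rep_len(condition_active, n)
  )
  out$chain <- chain_of(out$parameter, registry)
  out$latching <- out$priority_family == "physiologic" &
    out$priority_level == 3L & out$parameter %in% registry$latching
  out$yellow_class <- as.character(ifelse(
    out$priority_family == "physiologic" & out$priority_level == 2L,
    ifelse(out$parameter %in% registry$yellow_long, "long", "short"),
    NA_character_))
  out
}

# Severity ranking used by the announcement order:
# red > long yellow > short yellow > advisory > hard INOP > moderate INOP >
# soft INOP. The vendor's stated order covers red, the yellow classes and
# hard vs soft INOP; advisory physiologic alarms and moderate INOPs are
# slotted between their neighbours (patient-related above technical).
severity_rank <- function(alarms) {
  phys <- alarms$priority_family == "physiologic"
  rank <- numeric(nrow(alarms))
  rank[phys & alarms$priority_level == 3L] <- 70
  rank[phys & alarms$priority_level == 2L & alarms$yellow_class %in% "long"] <- 60
  rank[phys & alarms$priority_level == 2L & !(alarms$yellow_class %in% "long")] <- 50
  rank[phys & alarms$priority_level == 1L] <- 40
  rank[!phys & alarms$priority_level == 3L] <- 30
  rank[!phys & alarms$priority_level == 2L] <- 20
  rank[!phys & alarms$priority_level == 1L] <- 15
  rank[!phys & alarms$priority_level == 0L] <- 10
  rank
}

#' Announce concurrent active alarms
#'
#' Reproduces the central station's announcement behaviour for a set of
#' concurrent alarms. Alarms are grouped into priority chains (PVC, beat
#' detection, rate; everything else announces independently); only the
#' highest-severity alarm in each chain is a candidate, lower-severity
#' candidates are suppressed while a higher-priority alarm announces, and
#' an equal-severity conflict across chains resolves to the more recent
#' alarm. Announcement severity follows red > long yellow (in the presence
#' of any other yellow or INOP) > short yellow > hard INOP > soft INOP. A
#' long yellow alarm outranks short yellows only when another yellow or
#' INOP alarm is concurrently active; alone, it announces as an ordinary
#' yellow.
#'
#' A silenced (acknowledged) alarm whose condition persists stays on the
#' display without sound. The display list holds at most 10 alarms, ordered
#' by severity then recency; alarms beyond the cap are suppressed with
#' reason `display_cap_10`.
#'
#' @param active Tibble from [active_alarms()].
#' @param now POSIXct evaluation time (used only for bookkeeping).
#' @param paused Suppress all audio (an active alarm pause)?
#' @return An `announcement` list: `announced` (zero- or one-row tibble
#'   with `audible`), `display_list` (tibble, at most 10 rows), and
#'   `suppressed` (tibble of `alarm_id`, `parameter`, `reason`).
#' @export
announce <- function(active, now = Sys.time(), paused = FALSE) {
  stopifnot(is.data.frame(active))
  if (nrow(active) == 0) {
    return(structure(list(announced = active, display_list = active,
                          suppressed = tibble::tibble(alarm_id = integer(),
                                                      parameter = character(),
                                                      reason = character())),
                     class = "announcement"))
  }
  act <- active
  # a lone long yellow with no other yellow/INOP behaves as a plain yellow
  other_yellow_or_inop <- function(i) {
    any((act$priority_family[-i] == "technical") |
          (act$priority_family[-i] == "physiologic" &
             act$priority_level[-i] == 2L))
  }
  act$eff_yellow_class <- act$yellow_class
  for (i in which(act$yellow_class %in% "long")) {
    if (!other_yellow_or_inop(i)) act$eff_yellow_class[i] <- "short"
  }
  rank_in <- act
  rank_in$yellow_class <- act$eff_yellow_class
  act$severity <- severity_rank(rank_in)

  suppressed <- list()
  supp <- function(rows, reason) {
    if (length(rows) > 0) {
      suppressed[[length(suppressed) + 1]] <<- tibble::tibble(
        alarm_id = act$alarm_id[rows], parameter = act$parameter[rows],
        reason = reason)
    }
  }

  # chain "none" alarms announce independently: each is its own chain
  chain_id <- ifelse(act$chain == "none",
                     paste0("none#", act$alarm_id), act$chain)
  is_top <- rep(FALSE, nrow(act))
  for (ch in unique(chain_id)) {
    rows <- which(chain_id == ch)
    o <- rows[order(-act$severity[rows], as.numeric(act$onset_ts[rows]) * -1)]
    is_top[o[1]] <- TRUE
    supp(o[-1], "outranked_in_chain")
  }

  cand <- which(is_top)
  top_sev <- max(act$severity[cand])
  below <- cand[act$severity[cand] < top_sev]
  supp(below, "lower_priority_than_announced")
  eq <- cand[act$severity[cand] == top_sev]
  if (length(eq) > 1) {
    o <- eq[order(as.numeric(act$onset_ts[eq]), act$alarm_id[eq])]
    winner <- o[length(o)] # equal severity: the more recent alarm announces
    supp(setdiff(eq, winner), "older_equal_severity")
  } else {
    winner <- eq
  }

  announced <- act[winner, , drop = FALSE]
  announced$audible <- !announced$acknowledged & !paused &
    (announced$condition_active | announced$latching)

  disp_order <- order(-act$severity, -as.numeric(act$onset_ts), act$alarm_id)
  display_list <- act[disp_order, , drop = FALSE]
  if (nrow(display_list) > 10) {
    over <- display_list$alarm_id[-(1:10)]
    supp(match(over, act$alarm_id), "display_cap_10")
    display_list <- display_list[1:10, , drop = FALSE]
  }

  suppressed <- if (length(suppressed) > 0) dplyr::bind_rows(suppressed) else {
    tibble::tibble(alarm_id = integer(), parameter = character(),
                   reason = character())
  }
  structure(list(announced = announced, display_list = display_list,
                 suppressed = suppressed, now = now),
            class = "announcement")
}

#' @export
print.announcement <- function(x, ...) {
  if (nrow(x$announced) > 0) {
    cat("Announced:", x$announced$parameter,
        if (isTRUE(x$announced$audible)) "(audible)" else "(silent)", "\n")
  } else {
    cat("Announced: none\n")
  }
  cat("Displayed:", nrow(x$display_list), "alarm(s); suppressed:",
      nrow(x$suppressed), "\n")
  invisible(x)
}

#' Create a monitor alarm state for the action simulator
#'
#' @param active Tibble from [active_alarms()].
#' @param yellow_pause_only Site configuration: does "All Alarms Off" /
#'   pause apply to yellow alarms only (red alarms keep sounding)?
#' @return A `monitor_state` list.
#' @export
monitor_state <- function(active, yellow_pause_only = FALSE) {
  structure(list(active = active, paused_until = NULL,
                 yellow_pause_only = yellow_pause_only),
            class = "monitor_state")
}

#' Apply a clinician action to the monitor state
#'
#' `Silence` acknowledges the currently announced alarm: the audio and
#' alarm lamp turn off while the flashing numeric persists (the alarm stays
#' in the display), and an audible reminder may later be logged as a
#' separate event. `Pause` suppresses audio for the given duration (`Inf`
#' disables alarms until `Resume`); in the yellow-only configuration red
#' alarms keep sounding through a pause. `Resume` clears the pause.
#'
#' @param state A `monitor_state`.
#' @param action One of `"Silence"`, `"Pause"`, `"Resume"`.
#' @param now POSIXct time of the action.
#' @param duration_s Pause duration in seconds (may be `Inf`).
#' @return The updated `monitor_state`.
#' @export
apply_user_action <- function(state, action, now = Sys.time(),
                              duration_s = 120) {
  stopifnot(inherits(state, "monitor_state"))
  if (!action %in% c("Silence", "Pause", "Resume")) {
    stop("unknown user action for the simulator: ", action, call. = FALSE)
  }
  if (action == "Silence") {
    res <- announce(state$active, now, paused = is_paused(state, now))
    if (nrow(res$announced) > 0) {
      hit <- state$active$alarm_id %in% res$announced$alarm_id
      state$active$acknowledged[hit] <- TRUE
    }
  } else if (action == "Pause") {
    state$paused_until <- if (is.infinite(duration_s)) Inf else
      as.numeric(now) + duration_s
  } else {
    state$paused_until <- NULL
  }
  state
}

is_paused <- function(state, now) {
  !is.null(state$paused_until) &&
    (is.infinite(state$paused_until) || as.numeric(now) < state$paused_until)
}

#' End an alarm condition in the simulator
#'
#' Non-latching alarms reset when the condition ends and leave the active
#' set. Latching alarms — high-priority red alarms such as asystole and
#' ventricular fibrillation — keep sounding even after the condition is no
#' longer present and remain active until a clinician silences them;
#' ending the condition of an already-acknowledged latching alarm removes
#' it.
#'
#' @param state A `monitor_state`.
#' @param alarm_id Identifier(s) of the alarm(s) whose condition ended.
#' @return The updated `monitor_state`.
#' @export
end_condition <- function(state, alarm_id) {
  stopifnot(inherits(state, "monitor_state"))
  hit <- state$active$alarm_id %in% alarm_id
  state$active$condition_active[hit] <- FALSE
  drop <- hit & (!state$active$latching | state$active$acknowledged)
  state$active <- state$active[!drop, , drop = FALSE]
  state
}

#' Evaluate the current announcement of a monitor state
#'
#' @param state A `monitor_state`.
#' @param now POSIXct evaluation time.
#' @return An `announcement`; see [announce()]. With the yellow-only pause
#'   configuration, a pause leaves red alarms audible.
#' @export
state_announce <- function(state, now = Sys.time()) {
  paused <- is_paused(state, now)
  if (paused && state$yellow_pause_only) {
    res <- announce(state$active, now, paused = FALSE)
    if (nrow(res$announced) > 0) {
      is_red <- res$announced$priority_family == "physiologic" &
        res$announced$priority_level == 3L
      res$announced$audible <- res$announced$audible & is_red
    }
    return(res)
  }
  announce(state$active, now, paused = paused)
}
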