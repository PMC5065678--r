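#' Pair alarm generation/end events into episodes
#'
#' The audit log records the generation and the end of an alarm as separate,
#' unconnected rows; alarm duration — the key proxy for clinician response
#' time — requires pairing them. Events are stably sorted by patient
#' identity, bed, device, parameter, priority and time (ties break by file
#' order, since the log is chronological), and each `Ended` is matched to
#' the nearest preceding unmatched `Generated` with the same key.
#'
#' For alarms that signalled for less than a second the device logs the end
#' time *before* the generation time; an `Ended` with no open `Generated`
#' that is followed, within the same key and second, by a `Generated` pairs
#' with it as a zero-duration episode. A `Generated` never followed by an
#' `Ended` is right-censored at the window end; an `Ended` with no
#' preceding `Generated` is left-censored at the window start. Censored
#' events are also listed in the unmatched report with their source rows.
#'
#' The matching key includes priority, so the same parameter alarming at
#' different priorities forms distinct episode streams (both `*HR` and
#' `**HR` occur in practice and are distinct audible experiences). A masked
#' MRN (all zeros or empty) falls back to bed + device as the identity.
#'
#' @param events Parsed event tibble from [parse_events()]. Non-alarm rows
#'   (sounds, actions, unparsed) are ignored.
#' @param window Optional `c(start, end)` POSIXct pair bounding the
#'   observation window; defaults to the range of the alarm timestamps.
#' @return A list with `episodes` (tibble: key columns, `start_ts`,
#'   `end_ts`, `duration_s`, `start_value`, `end_value`, `left_censored`,
#'   `right_censored`, `start_row`, `end_row`) and `unmatched` (tibble of
#'   anomalies: `row_index`, `reason`).
#' @export
pair_episodes <- function(events, window = NULL) {
  alarms <- dplyr::filter(
    events,
    .data$event_type %in% c("physiologic", "technical"),
    .data$status %in% c("generated", "ended")
  )
  if (nrow(alarms) == 0) {
    return(list(episodes = empty_episodes(), unmatched = empty_unmatched()))
  }
  if (is.null(window)) {
    window <- range(alarms$timestamp)
  }
  stopifnot(length(window) == 2, window[1] <= window[2])

  identity <- episode_identity(alarms$mrn, alarms$bed_label, alarms$device_name)
  key <- paste(identity, alarms$bed_label, alarms$device_name,
               alarms$parameter, alarms$priority_family, alarms$priority_level,
               sep = "\r")
  ord <- order(key, alarms$timestamp, alarms$row_index, method = "radix")
  alarms <- alarms[ord, ]
  key <- key[ord]

  eps <- list()
  unmatched <- list()
  for (idx in split(seq_len(nrow(alarms)), key)) {
    grp <- alarms[idx, ]
    n <- nrow(grp)
    consumed <- rep(FALSE, n)
    open <- integer() # stack of unmatched Generated positions
    for (i in seq_len(n)) {
      if (consumed[i]) next
      if (grp$status[i] == "generated") {
        open <- c(open, i)
        next
      }
      # an Ended row
      if (length(open) > 0) {
        g <- open[length(open)]
        open <- open[-length(open)]
        eps[[length(eps) + 1]] <- make_episode(grp, g, i)
        consumed[c(g, i)] <- TRUE
      } else {
        # inversion path: Generated logged after its sub-second Ended,
        # within the same second
        ahead <- which(!consumed & grp$status == "generated" &
                         seq_len(n) > i &
                         grp$timestamp == grp$timestamp[i])
        if (length(ahead) > 0) {
          g <- ahead[1]
          ep <- make_episode(grp, g, i)
          ep$start_ts <- grp$timestamp[g]
          ep$end_ts <- grp$timestamp[g] # sub-second: duration rounds to 0 s
          ep$duration_s <- 0
          eps[[length(eps) + 1]] <- ep
          consumed[c(g, i)] <- TRUE
        } else {
          ep <- make_episode(grp, NA, i)
          ep$start_ts <- window[1]
          ep$duration_s <- as.numeric(grp$timestamp[i]) - as.numeric(window[1])
          ep$left_censored <- TRUE
          eps[[length(eps) + 1]] <- ep
          consumed[i] <- TRUE
          unmatched[[length(unmatched) + 1]] <-
            list(row_index = grp$row_index[i], reason = "ended_without_generated")
        }
      }
    }
    for (g in open) {
      ep <- make_episode(grp, g, NA)
      ep$end_ts <- window[2]
      ep$duration_s <- as.numeric(window[2]) - as.numeric(grp$timestamp[g])
      ep$right_censored <- TRUE
      eps[[length(eps) + 1]] <- ep
      unmatched[[length(unmatched) + 1]] <-
        list(row_index = grp$row_index[g], reason = "generated_without_ended")
    }
  }

  episodes <- dplyr::bind_rows(eps)
  if (nrow(episodes) == 0) episodes <- empty_episodes()
  episodes <- dplyr::arrange(episodes, .data$start_ts, .data$bed_label,
                             .data$parameter, .data$start_row)
  unmatched <- if (length(unmatched) > 0) {
    dplyr::arrange(dplyr::bind_rows(unmatched), .data$row_index)
  } else {
    empty_unmatched()
  }
  list(episodes = episodes, unmatched = unmatched)
}

make_episode <- function(grp, g, e) {
  has_g <- !is.na(g); has_e <- !is.na(e)
  ref <- if (has_g) g else e
  tibble::tibble(
    mrn = grp$mrn[ref],
    bed_label = grp$bed_label[ref],
    device_name = grp$device_name[ref],
    parameter = grp$parameter[ref],
    priority_family = grp$priority_family[ref],
    priority_level = grp$priority_level[ref],
    start_ts = if (has_g) grp$timestamp[g] else as.POSIXct(NA, tz = "UTC"),
    end_ts = if (has_e) grp$timestamp[e] else as.POSIXct(NA, tz = "UTC"),
    duration_s = if (has_g && has_e) {
      as.numeric(grp$timestamp[e]) - as.numeric(grp$timestamp[g])
    } else NA_real_,
    start_value = if (has_g) grp$value[g] else NA_real_,
    end_value = if (has_e) grp$value[e] else NA_real_,
    left_censored = FALSE,
    right_censored = FALSE,
    start_row = if (has_g) grp$row_index[g] else NA_integer_,
    end_row = if (has_e) grp$row_index[e] else NA_integer_
  )
}

empty_episodes <- function() {
  tibble::tibble(
    mrn = character(), bed_label = character(), device_name = character(),
    parameter = character(), priority_family = character(),
    priority_level = integer(),
    start_ts = as.POSIXct(character(), tz = "UTC"),
    end_ts = as.POSIXct(character(), tz = "UTC"),
    duration_s = double(), start_value = double(), end_value = double(),
    left_censored = logical(), right_censored = logical(),
    start_row = integer(), end_row = integer()
  )
}

empty_unmatched <- function() {
  tibble::tibble(row_index = integer(), reason = character())
}

# masked MRNs (all zeros, empty, NA) identify nothing; fall back to bed+device
episode_identity <- function(mrn, bed_label, device_name) {
  masked <- is.na(mrn) | mrn == "" | grepl("^0+$", mrn)
  ifelse(masked, paste(bed_label, device_name, sep = "|"), mrn)
}

#' Check episode conservation
#'
#' Verifies the bookkeeping identity of [pair_episodes()]: the number of
#' episodes equals the number of `Generated` events consumed plus the
#' number of left-censored episodes, and every alarm event row appears in
#' exactly one episode or in the unmatched report.
#'
#' @param events Parsed event tibble handed to [pair_episodes()].
#' @param pairing The list returned by [pair_episodes()].
#' @return A list with `ok` (logical) and `details` (tibble diff of any
#'   violations, empty when `ok`).
#' @export
episode_conservation_check <- function(events, pairing) {
  episodes <- pairing$episodes
  alarms <- dplyr::filter(
    events,
    .data$event_type %in% c("physiologic", "technical"),
    .data$status %in% c("generated", "ended")
  )
  n_gen_consumed <- sum(!is.na(episodes$start_row))
  n_left <- sum(episodes$left_censored)
  count_ok <- n_gen_consumed + n_left == nrow(episodes)

  covered <- c(episodes$start_row, episodes$end_row, pairing$unmatched$row_index)
  covered <- covered[!is.na(covered)]
  missing <- setdiff(alarms$row_index, covered)
  dup_rows <- c(episodes$start_row, episodes$end_row)
  dup_rows <- dup_rows[!is.na(dup_rows)]
  dups <- dup_rows[duplicated(dup_rows)]

  details <- dplyr::bind_rows(
    if (!count_ok) tibble::tibble(
      row_index = NA_integer_,
      problem = sprintf("episode count %d != generated consumed %d + left censored %d",
                        nrow(episodes), n_gen_consumed, n_left)),
    if (length(missing) > 0) tibble::tibble(
      row_index = as.integer(missing), problem = "alarm event in no episode or report"),
    if (length(dups) > 0) tibble::tibble(
      row_index = as.integer(dups), problem = "alarm event in more than one episode")
  )
  if (is.null(details)) details <- tibble::tibble(row_index = integer(),
                                                  problem = character())
  list(ok = nrow(details) == 0, details = details)
}
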