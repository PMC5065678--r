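#' Default alarm catalogue for the synthetic generator
#'
#' The record mix a unit audit log exhibits: numerical yellow/red limit
#' alarms (HR, Desat, ABPs, PAPd, RR, SpO2), categorical advisory
#' arrhythmia alarms, a soft and a moderate INOP, with default per-bed-day
#' event rates of the order seen on a busy cardiac ICU. Rates are
#' events/bed-day; limits are the programmed default settings the messages
#' print.
#'
#' @return Tibble with columns `parameter`, `family`, `level`, `kind`,
#'   `direction`, `limit`, `rate`.
#' @export
synth_alarm_catalog <- function() {
  tibble::tribble(
    ~parameter, ~family, ~level, ~kind, ~direction, ~limit, ~rate,
    "HR",             "physiologic", 2L, "numerical",  "above", 150, 12,
    "Desat",          "physiologic", 3L, "numerical",  "below",  88,  6,
    "ABPs",           "physiologic", 2L, "numerical",  "above", 160,  8,
    "PAPd",           "physiologic", 2L, "numerical",  "above",  16,  4,
    "RR",             "physiologic", 2L, "numerical",  "above",  30, 10,
    "SpO2",           "physiologic", 2L, "numerical",  "below",  90,  8,
    "Multiform PVCs", "physiologic", 1L, "categorical", NA,      NA,  5,
    "AFIB",           "physiologic", 1L, "categorical", NA,      NA,  2,
    "Irregular Heart Rate", "physiologic", 1L, "categorical", NA, NA,  3,
    "ECG Leads Off",  "technical",   0L, "categorical", NA,      NA,  3,
    "Batt Empty",     "technical",   2L, "categorical", NA,      NA,  1
  )
}

#' Configuration for the synthetic audit-log generator
#'
#' @param n_beds Number of monitored beds (default 20, a typical unit).
#' @param start Window start (POSIXct).
#' @param duration_days Window length in days.
#' @param catalog Alarm catalogue tibble (see [synth_alarm_catalog()]);
#'   its `rate` column sets the per-parameter Poisson intensity in
#'   events/bed-day.
#' @param action_rates Named vector of clinician-action rates per bed-day.
#' @param mean_duration_s Mean episode duration (exponential), seconds.
#' @param p_subsecond Probability an episode lasts under a second, in
#'   which case the device logs its end *before* its generation within
#'   the same second.
#' @param unsafe_limits Optional tibble (`bed_label`, `parameter`,
#'   `direction`, `limit`, `level`, `n`) of planted unsafe limit settings.
#' @param priority_inconsistencies Optional character vector of numerical
#'   catalogue parameters; for each, one alarm pair is emitted at priority
#'   1 alongside the regular priority, planting one inconsistency per
#'   parameter.
#' @param disabled_alarms Optional list(`parameter` =, `beds` =) planting
#'   supposedly disabled alarms on non-compliant beds.
#' @param gaps Optional tibble (`start`, `end`) of connectivity-loss
#'   intervals whose records are deleted (and noted in the manifest).
#' @param device_name Information Center host name stamped on each row.
#' @param seed Integer; fully determines the output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_beds = 20,
                         start = as.POSIXct("2014-04-20 00:00:00", tz = "UTC"),
                         duration_days = 1,
                         catalog = synth_alarm_catalog(),
                         action_rates = c("Silence" = 10,
                                          "Pause All Alarms" = 1,
                                          "Resume All Alarms" = 1,
                                          "Alarm Limit Change" = 0.5,
                                          "Transfer" = 0.2),
                         mean_duration_s = 30,
                         p_subsecond = 0.1,
                         unsafe_limits = NULL,
                         priority_inconsistencies = NULL,
                         disabled_alarms = NULL,
                         gaps = NULL,
                         device_name = "PIIC iX: ixsurv006",
                         seed = 1L) {
  stopifnot(n_beds >= 1, duration_days > 0, all(catalog$rate >= 0),
            all(action_rates >= 0), mean_duration_s > 0,
            p_subsecond >= 0, p_subsecond <= 1)
  structure(
    list(n_beds = n_beds, start = start, duration_days = duration_days,
         catalog = catalog, action_rates = action_rates,
         mean_duration_s = mean_duration_s, p_subsecond = p_subsecond,
         unsafe_limits = unsafe_limits,
         priority_inconsistencies = priority_inconsistencies,
         disabled_alarms = disabled_alarms, gaps = gaps,
         device_name = device_name, seed = as.integer(seed)),
    class = "synth_config")
}

#' Generate a synthetic unit audit log with ground truth
#'
#' Draws alarm episodes as Poisson streams per parameter and bed, emits a
#' `Generated` and an `Ended` row per episode (sub-second episodes emit the
#' end before the generation, reproducing the device's logging inversion),
#' interleaves alarm-sound events (red/yellow for audible physiologic
#' alarms, INOP sound for moderate/hard INOPs; soft INOPs are silent) and
#' clinician actions, and applies any planted anomalies and connectivity
#' gaps. MRNs are emitted as zeros, mirroring a masked export.
#'
#' Episodes of the same (bed, parameter, priority) stream never overlap —
#' an alarm condition cannot regenerate while it is active — so parsing the
#' emitted log and pairing it reproduces the ground-truth episodes exactly
#' (absent planted gaps).
#'
#' @param config A [synth_config()].
#' @return A list: `records` (tibble in the audit-record layout of
#'   [read_audit_log()], in log order) and `truth` (list with `episodes`,
#'   `action_counts`, `rates`, `bed_days`, and the planted-anomaly
#'   `manifest`).
#' @export
generate_log <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_log_impl(config))
}

generate_log_impl <- function(cfg) {
  t0 <- as.numeric(cfg$start)
  span_s <- cfg$duration_days * 86400
  beds <- sprintf("%d-S1", 9000 + 2 * seq_len(cfg$n_beds) + 75)
  rows <- list()
  eps <- list()

  emit <- function(ts, bed, msg, sub) {
    rows[[length(rows) + 1]] <<- list(ts = ts, bed = bed, msg = msg, sub = sub)
  }
  sub_counter <- 0
  next_sub <- function() {
    sub_counter <<- sub_counter + 1
    sub_counter
  }

  emit_episode <- function(bed, par, fam, level, kind, direction, limit,
                           onset, duration) {
    marks <- if (fam == "physiologic") strrep("*", level) else strrep("!", level)
    gen_ts <- floor(onset)
    end_ts <- floor(onset + duration)
    zero <- end_ts <= gen_ts
    if (zero) end_ts <- gen_ts
    if (kind == "numerical") {
      delta <- sample(1:15, 2, replace = TRUE)
      val_g <- if (direction == "above") limit + delta[1] else max(0, limit - delta[1])
      val_e <- if (direction == "above") limit + 1 else max(0, limit - 1)
      cmp <- if (direction == "above") ">" else "<"
      gen_msg <- sprintf("%s%s %s %s%s Generated.", marks, par, format_num(val_g),
                         cmp, format_num(limit))
      end_msg <- sprintf("%s%s %s %s%s Ended.", marks, par, format_num(val_e),
                         cmp, format_num(limit))
    } else {
      val_g <- NA_real_; val_e <- NA_real_
      gen_msg <- sprintf("%s%s Generated.", marks, par)
      end_msg <- sprintf("%s%s Ended.", marks, par)
    }
    s1 <- next_sub(); s2 <- next_sub()
    if (zero) { tmp <- s1; s1 <- s2; s2 <- tmp } # end logged before generation
    emit(gen_ts, bed, gen_msg, s1)
    emit(end_ts, bed, end_msg, s2)
    sound <- alarm_sound(fam, level)
    if (!is.na(sound)) emit(gen_ts, bed, sound, next_sub())
    eps[[length(eps) + 1]] <<- list(
      bed_label = bed, parameter = par, priority_family = fam,
      priority_level = level, start_s = gen_ts, end_s = end_ts,
      duration_s = end_ts - gen_ts, start_value = val_g, end_value = val_e)
  }

  draw_stream <- function(bed, par, fam, level, kind, direction, limit, rate) {
    n <- rpois(1, rate * cfg$duration_days)
    if (n == 0) return(invisible())
    onsets <- sort(t0 + runif(n, 0, span_s - 1))
    prev_end <- -Inf
    for (o in onsets) {
      sub <- runif(1) < cfg$p_subsecond
      dur <- if (sub) 0 else 1 + rexp(1, 1 / cfg$mean_duration_s)
      o <- max(o, prev_end + 2) # same-stream episodes never overlap
      emit_episode(bed, par, fam, level, kind, direction, limit, o, dur)
      prev_end <- floor(o + dur)
    }
  }

  for (b in beds) {
    for (i in seq_len(nrow(cfg$catalog))) {
      p <- cfg$catalog[i, ]
      draw_stream(b, p$parameter, p$family, p$level, p$kind, p$direction,
                  p$limit, p$rate)
    }
  }

  # clinician actions
  action_truth <- integer(0)
  for (kind in names(cfg$action_rates)) {
    n <- rpois(1, cfg$action_rates[[kind]] * cfg$n_beds * cfg$duration_days)
    action_truth[kind] <- n
    if (n == 0) next
    ts <- floor(t0 + runif(n, 0, span_s - 1))
    bed <- sample(beds, n, replace = TRUE)
    msg <- switch(kind,
      "Silence" = rep("Silence.", n),
      "Pause All Alarms" = rep("Pause All Alarms.", n),
      "Resume All Alarms" = rep("Resume All Alarms.", n),
      "Alarm Limit Change" = sprintf("SpO2: Desat Limit %d.",
                                     sample(85:92, n, replace = TRUE)),
      "Transfer" = sprintf("Patient transferred to %s.",
                           sample(beds, n, replace = TRUE)),
      stop("no message template for action kind: ", kind, call. = FALSE))
    for (j in seq_len(n)) emit(ts[j], bed[j], msg[j], next_sub())
  }

  manifest <- list()

  if (!is.null(cfg$unsafe_limits)) {
    ul <- tibble::as_tibble(cfg$unsafe_limits)
    for (i in seq_len(nrow(ul))) {
      n <- if ("n" %in% names(ul)) ul$n[i] else 1L
      lev <- if ("level" %in% names(ul)) ul$level[i] else 3L
      for (j in seq_len(n)) {
        onset <- t0 + runif(1, 0, span_s - 120)
        emit_episode(ul$bed_label[i], ul$parameter[i], "physiologic", lev,
                     "numerical", ul$direction[i], ul$limit[i], onset,
                     1 + rexp(1, 1 / cfg$mean_duration_s))
      }
    }
    manifest$unsafe_limits <- ul
  }

  if (!is.null(cfg$priority_inconsistencies)) {
    for (par in cfg$priority_inconsistencies) {
      p <- cfg$catalog[cfg$catalog$parameter == par, ]
      stopifnot(nrow(p) == 1, p$kind == "numerical")
      bed2 <- sample(beds, 2, replace = TRUE)
      onset <- t0 + runif(2, 0, span_s - 120)
      # same condition signature (parameter, direction, limit), two priorities
      emit_episode(bed2[1], par, "physiologic", 1L, "numerical", p$direction,
                   p$limit, onset[1], 1 + rexp(1, 1 / cfg$mean_duration_s))
      emit_episode(bed2[2], par, "physiologic", 2L, "numerical", p$direction,
                   p$limit, onset[2], 1 + rexp(1, 1 / cfg$mean_duration_s))
    }
    manifest$priority_inconsistencies <- cfg$priority_inconsistencies
  }

  if (!is.null(cfg$disabled_alarms)) {
    da <- cfg$disabled_alarms
    for (b in da$beds) {
      onset <- t0 + runif(1, 0, span_s - 120)
      emit_episode(b, da$parameter, "physiologic", 1L, "categorical", NA, NA,
                   onset, 1 + rexp(1, 1 / cfg$mean_duration_s))
    }
    manifest$disabled_alarms <- da
  }

  df <- tibble::tibble(
    ts = vapply(rows, `[[`, numeric(1), "ts"),
    bed = vapply(rows, `[[`, character(1), "bed"),
    msg = vapply(rows, `[[`, character(1), "msg"),
    sub = vapply(rows, `[[`, numeric(1), "sub"))
  df <- df[order(df$ts, df$sub), ]
  episodes <- tibble::tibble(
    bed_label = vapply(eps, `[[`, character(1), "bed_label"),
    parameter = vapply(eps, `[[`, character(1), "parameter"),
    priority_family = vapply(eps, `[[`, character(1), "priority_family"),
    priority_level = vapply(eps, function(e) as.integer(e$priority_level),
                            integer(1)),
    start_s = vapply(eps, `[[`, numeric(1), "start_s"),
    end_s = vapply(eps, `[[`, numeric(1), "end_s"),
    duration_s = vapply(eps, `[[`, numeric(1), "duration_s"),
    start_value = vapply(eps, `[[`, numeric(1), "start_value"),
    end_value = vapply(eps, `[[`, numeric(1), "end_value"))
  if (nrow(episodes) > 0) {
    episodes$start_ts <- as.POSIXct(episodes$start_s, origin = "1970-01-01",
                                    tz = "UTC")
    episodes$end_ts <- as.POSIXct(episodes$end_s, origin = "1970-01-01",
                                  tz = "UTC")
    episodes$mrn <- "0000000"
    episodes$device_name <- cfg$device_name
    episodes <- episodes[order(episodes$start_s, episodes$bed_label,
                               episodes$parameter), ]
    episodes$start_s <- NULL; episodes$end_s <- NULL
  }

  if (!is.null(cfg$gaps) && nrow(df) > 0) {
    gp <- tibble::as_tibble(cfg$gaps)
    drop <- rep(FALSE, nrow(df))
    for (i in seq_len(nrow(gp))) {
      drop <- drop | (df$ts >= as.numeric(gp$start[i]) &
                        df$ts < as.numeric(gp$end[i]))
    }
    manifest$gaps <- gp
    manifest$records_lost_in_gaps <- sum(drop)
    df <- df[!drop, ]
  }

  records <- if (nrow(df) > 0) {
    tibble::tibble(
      timestamp = as.POSIXct(df$ts, origin = "1970-01-01", tz = "UTC"),
      bed_label = df$bed, mrn = "0000000", raw_message = df$msg,
      device_name = cfg$device_name, row_index = seq_len(nrow(df)))
  } else {
    empty_audit_log()
  }

  list(records = records,
       truth = list(episodes = episodes,
                    action_counts = action_truth,
                    rates = setNames(cfg$catalog$rate, cfg$catalog$parameter),
                    bed_days = cfg$n_beds * ceiling(cfg$duration_days),
                    manifest = manifest))
}

alarm_sound <- function(family, level) {
  if (family == "physiologic") {
    if (level == 3) "Red alarm sound played."
    else if (level == 2) "Yellow alarm sound played."
    else NA_character_ # advisory alarms announce visually
  } else {
    if (level >= 2) "INOP sound played." else NA_character_ # soft INOP: silent
  }
}

#' Write a generated log and its ground-truth manifest
#'
#' The records go to `path` in the canonical normalized CSV dialect of
#' [write_normalized()]; the manifest (planted anomalies, configured rates,
#' action counts) goes to `paste0(path, ".manifest.json")`.
#'
#' @param gen Output of [generate_log()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_synth_log <- function(gen, path) {
  write_normalized(gen$records, path)
  manifest <- gen$truth[c("action_counts", "rates", "bed_days", "manifest")]
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       POSIXt = "ISO8601")
  invisible(path)
}
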