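# Brute-force interval-matching oracle for episode pairing.
#
# For each key it enumerates every injective assignment of Ended events to
# candidate Generated events (a Generated at or before the Ended, or - the
# sub-second inversion - a Generated up to one second after it), scores
# each matching by (number of censored events, number of crossing pairs,
# total matched duration) and, among optima, prefers for each Ended in file
# order its temporally nearest candidate. Independent of pair_episodes():
# search over matchings rather than a single chronological scan.
oracle_pair_key <- function(grp) {
  n <- nrow(grp)
  ord <- order(grp$timestamp, grp$row_index)
  grp <- grp[ord, ]
  g_idx <- which(grp$status == "generated")
  e_idx <- which(grp$status == "ended")
  ts <- as.numeric(grp$timestamp)

  candidates <- lapply(e_idx, function(e) {
    before <- g_idx[g_idx < e]
    after <- g_idx[g_idx > e & ts[g_idx] == ts[e]]
    # nearest first: preceding Generated from latest to earliest, then the
    # earliest same-second later Generated
    c(rev(before), after)
  })

  best <- NULL
  best_score <- NULL
  assign_next <- function(k, used, partner) {
    if (k > length(e_idx)) {
      matched <- which(!is.na(partner))
      g_used <- partner[matched]
      # An end-before-generation pairing exists only for sub-second alarms:
      # it is admissible only when no alarm of the key was open at the
      # Ended's time, i.e. every preceding Generated is matched to an
      # earlier Ended. A matching violating this is not a valid reading of
      # the chronological log.
      for (j in matched) {
        e <- e_idx[j]
        if (partner[j] > e) {
          for (g0 in g_idx[g_idx < e]) {
            j0 <- match(g0, partner)
            if (is.na(j0) || e_idx[j0] >= e) return(invisible())
          }
        }
      }
      censored <- (length(e_idx) - length(matched)) +
        (length(g_idx) - length(matched))
      ivs <- cbind(pmin(ts[g_used], ts[e_idx[matched]]),
                   pmax(ts[g_used], ts[e_idx[matched]]))
      crossings <- 0
      if (nrow(ivs) > 1) {
        for (a in seq_len(nrow(ivs) - 1)) {
          for (b in (a + 1):nrow(ivs)) {
            s1 <- ivs[a, 1]; e1 <- ivs[a, 2]; s2 <- ivs[b, 1]; e2 <- ivs[b, 2]
            if ((s1 < s2 && s2 < e1 && e1 < e2) ||
                (s2 < s1 && s1 < e2 && e2 < e1)) crossings <- crossings + 1
          }
        }
      }
      total <- sum(abs(ts[e_idx[matched]] - ts[g_used]))
      # tiebreak: prefer nearest candidates, encoded as the preference rank
      # of each Ended's partner in its candidate list
      pref <- vapply(seq_along(e_idx), function(j) {
        if (is.na(partner[j])) 99L else match(partner[j], candidates[[j]])
      }, integer(1))
      score <- list(censored = censored, crossings = crossings,
                    total = total, pref = pref)
      if (is.null(best_score) || score_less(score, best_score)) {
        best_score <<- score
        best <<- partner
      }
      return(invisible())
    }
    for (g in candidates[[k]]) {
      if (!used[g]) {
        used[g] <- TRUE
        partner[k] <- g
        assign_next(k + 1, used, partner)
        used[g] <- FALSE
        partner[k] <- NA_integer_
      }
    }
    assign_next(k + 1, used, partner) # leave this Ended unmatched
  }
  assign_next(1, rep(FALSE, n), rep(NA_integer_, length(e_idx)))

  pairs <- lapply(which(!is.na(best)), function(j) {
    list(start_row = grp$row_index[best[j]], end_row = grp$row_index[e_idx[j]])
  })
  list(
    pairs = pairs,
    censored_gen = grp$row_index[setdiff(g_idx, best[!is.na(best)])],
    censored_end = grp$row_index[e_idx[is.na(best)]]
  )
}

score_less <- function(a, b) {
  if (a$censored != b$censored) return(a$censored < b$censored)
  if (a$crossings != b$crossings) return(a$crossings < b$crossings)
  if (a$total != b$total) return(a$total < b$total)
  cmp <- a$pref - b$pref
  nz <- which(cmp != 0)
  if (length(nz) == 0) FALSE else cmp[nz[1]] < 0
}

oracle_pairing <- function(events) {
  alarms <- events[events$event_type %in% c("physiologic", "technical") &
                     events$status %in% c("generated", "ended"), ]
  masked <- is.na(alarms$mrn) | alarms$mrn == "" | grepl("^0+$", alarms$mrn)
  id <- ifelse(masked, paste(alarms$bed_label, alarms$device_name), alarms$mrn)
  key <- paste(id, alarms$bed_label, alarms$device_name, alarms$parameter,
               alarms$priority_family, alarms$priority_level)
  out <- lapply(split(seq_len(nrow(alarms)), key),
                function(idx) oracle_pair_key(alarms[idx, ]))
  pairs <- do.call(rbind, lapply(out, function(o) {
    if (length(o$pairs) == 0) return(NULL)
    do.call(rbind, lapply(o$pairs, function(p) {
      data.frame(start_row = p$start_row, end_row = p$end_row)
    }))
  }))
  list(
    pairs = if (is.null(pairs)) {
      data.frame(start_row = integer(), end_row = integer())
    } else pairs,
    censored_gen = sort(unlist(lapply(out, `[[`, "censored_gen"), use.names = FALSE)),
    censored_end = sort(unlist(lapply(out, `[[`, "censored_end"), use.names = FALSE))
  )
}

# compare pair_episodes() output with the oracle on the same events
expect_matches_oracle <- function(events) {
  res <- pair_episodes(events)
  orc <- oracle_pairing(events)
  got_pairs <- res$episodes[!is.na(res$episodes$start_row) &
                              !is.na(res$episodes$end_row),
                            c("start_row", "end_row")]
  got <- sort(paste(got_pairs$start_row, got_pairs$end_row))
  want <- sort(paste(orc$pairs$start_row, orc$pairs$end_row))
  expect_identical(got, want)
  expect_identical(sort(res$episodes$start_row[res$episodes$right_censored]),
                   as.integer(orc$censored_gen))
  expect_identical(sort(res$episodes$end_row[res$episodes$left_censored]),
                   as.integer(orc$censored_end))
  invisible(res)
}

# random small alarm log built from well-formed episodes with occasional
# dropped endpoints and sub-second inversions
random_small_log <- function(n_episodes = 8, n_keys = 3, span_s = 600,
                             p_drop = 0.15, p_subsecond = 0.25) {
  n_keys <- min(3, max(n_keys, ceiling(n_episodes / 4)))
  params <- c("HR", "Desat", "RR")[seq_len(n_keys)]
  # spread episodes over keys to keep the exhaustive oracle tractable
  assignment <- sample(rep_len(params, n_episodes))
  rows <- list()
  for (i in seq_len(n_episodes)) {
    par <- assignment[i]
    lev <- if (par == "Desat") 3L else 2L
    start <- sample.int(span_s, 1)
    dur <- if (runif(1) < p_subsecond) 0L else sample.int(120, 1)
    marks <- strrep("*", lev)
    gen <- list(ts = start, msg = sprintf("%s%s 100 >90 Generated.", marks, par),
                sub = if (dur == 0) 2 * i + 1 else 2 * i)
    end <- list(ts = start + dur, msg = sprintf("%s%s 91 >90 Ended.", marks, par),
                sub = if (dur == 0) 2 * i else 2 * i + 1)
    keep <- runif(2) > p_drop
    if (keep[1]) rows[[length(rows) + 1]] <- gen
    if (keep[2]) rows[[length(rows) + 1]] <- end
  }
  if (length(rows) == 0) return(events_from_messages(character(), ts_utc(character())))
  ts0 <- ts_utc("2014-04-20 00:00:00")
  o <- order(vapply(rows, `[[`, numeric(1), "ts"),
             vapply(rows, `[[`, numeric(1), "sub"))
  rows <- rows[o]
  events_from_messages(
    vapply(rows, `[[`, character(1), "msg"),
    ts0 + vapply(rows, `[[`, numeric(1), "ts")
  )
}

# Independent evaluation of the announcement ordering rules for small sets:
# rank every alarm by the stated severity ladder, keep chain winners, pick
# the global winner by severity then recency.
oracle_announce <- function(active) {
  sev <- vapply(seq_len(nrow(active)), function(i) {
    a <- active[i, ]
    other_y_or_inop <- any(active$priority_family[-i] == "technical" |
                             (active$priority_family[-i] == "physiologic" &
                                active$priority_level[-i] == 2L))
    if (a$priority_family == "physiologic") {
      if (a$priority_level == 3) 7
      else if (a$priority_level == 2 &&
               identical(a$yellow_class, "long") && other_y_or_inop) 6
      else if (a$priority_level == 2) 5
      else 4
    } else {
      if (a$priority_level == 3) 3 else if (a$priority_level == 2) 2 else 1
    }
  }, double(1))
  chain <- ifelse(active$chain == "none",
                  paste0("none", seq_len(nrow(active))), active$chain)
  winners <- vapply(unique(chain), function(ch) {
    rows <- which(chain == ch)
    rows[order(-sev[rows], -as.numeric(active$onset_ts[rows]))][1]
  }, integer(1))
  top <- winners[order(-sev[winners], -as.numeric(active$onset_ts[winners]),
                       active$alarm_id[winners])][1]
  active$alarm_id[top]
}
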