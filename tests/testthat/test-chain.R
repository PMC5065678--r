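now0 <- as.POSIXct("2014-04-20 12:00:00", tz = "UTC")

test_that("a single alarm announces and is displayed", {
  a <- active_alarms("HR", 2L, onset_ts = now0)
  res <- announce(a, now0)
  expect_equal(res$announced$parameter, "HR")
  expect_true(res$announced$audible)
  expect_equal(nrow(res$display_list), 1)
  expect_equal(nrow(res$suppressed), 0)
})

test_that("a lower-priority alarm is suppressed while a higher one is announced", {
  # Paired PVCs announced; a newly detected lower-priority Pause alarm is not
  a <- active_alarms(c("Paired PVCs", "Pause"), priority_level = c(2L, 1L),
                     onset_ts = now0 + c(0, 30))
  res <- announce(a, now0 + 60)
  expect_equal(res$announced$parameter, "Paired PVCs")
  pause_row <- res$suppressed[res$suppressed$parameter == "Pause", ]
  expect_equal(pause_row$reason, "lower_priority_than_announced")
})

test_that("the display list caps at 10 alarms with overflow recorded", {
  a <- active_alarms(paste0("P", 1:12), priority_level = rep(c(3L, 2L, 1L), 4),
                     onset_ts = now0 + 1:12)
  res <- announce(a, now0 + 20)
  expect_equal(nrow(res$display_list), 10)
  expect_equal(sum(res$suppressed$reason == "display_cap_10"), 2)
  # severity-ordered: no capped-out alarm outranks a displayed one
  capped <- res$suppressed$alarm_id[res$suppressed$reason == "display_cap_10"]
  expect_false(any(capped %in% res$display_list$alarm_id))
  expect_true(!is.unsorted(rev(res$display_list$severity)))
})

test_that("only the top alarm in each chain announces", {
  # two PVC-chain alarms: only one candidate from the chain
  a <- active_alarms(c("Multiform PVCs", "Pair PVCs"), priority_level = c(1L, 2L),
                     onset_ts = now0 + c(0, 10))
  res <- announce(a, now0 + 20)
  expect_equal(res$announced$parameter, "Pair PVCs")
  expect_equal(res$suppressed$reason[res$suppressed$parameter == "Multiform PVCs"],
               "outranked_in_chain")
})

test_that("equal severity across chains resolves to the more recent alarm", {
  # two short yellows from different chains
  a <- active_alarms(c("Pair PVCs", "AFIB"), priority_level = c(2L, 2L),
                     onset_ts = now0 + c(0, 30))
  res <- announce(a, now0 + 60)
  expect_equal(res$announced$parameter, "AFIB")
  expect_equal(res$suppressed$reason[res$suppressed$parameter == "Pair PVCs"],
               "older_equal_severity")
})

test_that("announcement order runs red > yellow > hard INOP > soft INOP", {
  a <- active_alarms(c("Desat", "SpO2", "Check Equipment", "Noisy ECG"),
                     priority_level = c(3L, 2L, 3L, 0L),
                     priority_family = c("physiologic", "physiologic",
                                         "technical", "technical"),
                     onset_ts = now0 + c(0, 10, 20, 30))
  res <- announce(a, now0 + 60)
  expect_equal(res$announced$parameter, "Desat")
  # remove the red alarm: the yellow outranks both INOPs despite being older
  res2 <- announce(a[-1, ], now0 + 60)
  expect_equal(res2$announced$parameter, "SpO2")
  res3 <- announce(a[3:4, ], now0 + 60)
  expect_equal(res3$announced$parameter, "Check Equipment")
})

test_that("long yellows outrank short yellows only amid other yellow/INOP alarms", {
  # HR is a long yellow, AFIB a short (advisory-class parameter set to yellow)
  both <- active_alarms(c("HR", "Pair PVCs"), priority_level = c(2L, 2L),
                        onset_ts = now0 + c(0, 30))
  res <- announce(both, now0 + 60)
  # despite Pair PVCs being more recent, the long yellow wins
  expect_equal(res$announced$parameter, "HR")
})

test_that("announce matches exhaustive rule evaluation for small alarm sets", {
  withr::local_seed(99)
  pool <- c("HR", "Pair PVCs", "Asystole", "Desat", "RR", "Batt Empty",
            "Check Equipment", "Noisy ECG", "AFIB", "Multiform PVCs")
  for (i in 1:200) {
    n <- sample(1:6, 1)
    pars <- sample(pool, n)
    fam <- ifelse(pars %in% c("Batt Empty", "Check Equipment", "Noisy ECG"),
                  "technical", "physiologic")
    lev <- ifelse(fam == "technical", sample(c(0L, 2L, 3L), n, replace = TRUE),
                  sample(1:3, n, replace = TRUE))
    a <- active_alarms(pars, lev, fam, onset_ts = now0 + sample.int(600, n))
    expect_equal(announce(a, now0 + 700)$announced$alarm_id,
                 oracle_announce(a),
                 info = paste(pars, lev, collapse = "; "))
  }
})

test_that("adding a higher-severity alarm never promotes other chains' alarms", {
  withr::local_seed(7)
  base <- active_alarms(c("HR", "Pair PVCs", "Check Equipment"),
                        priority_level = c(2L, 1L, 2L),
                        priority_family = c("physiologic", "physiologic",
                                            "technical"),
                        onset_ts = now0 + c(0, 10, 20))
  before <- announce(base, now0 + 60)
  red <- active_alarms("Asystole", 3L, onset_ts = now0 + 30)
  red$alarm_id <- 99L
  after <- announce(dplyr::bind_rows(base, red), now0 + 60)
  expect_equal(after$announced$parameter, "Asystole")
  # everything announced before and not the new red is now suppressed or equal
  expect_true(all(setdiff(before$announced$alarm_id, 99L) %in%
                    c(after$suppressed$alarm_id, after$announced$alarm_id)))
})

test_that("determinism: identical state and action sequence reproduce results", {
  a <- active_alarms(c("HR", "Desat"), c(2L, 3L), onset_ts = now0 + c(0, 5))
  r1 <- announce(a, now0 + 10)
  r2 <- announce(a, now0 + 10)
  expect_identical(r1$announced, r2$announced)
  expect_identical(r1$suppressed, r2$suppressed)
})

test_that("silencing turns audio off but keeps the persisting alarm displayed", {
  st <- monitor_state(active_alarms("Desat", 3L, onset_ts = now0))
  st <- apply_user_action(st, "Silence", now = now0 + 5)
  res <- state_announce(st, now0 + 10)
  expect_false(res$announced$audible)
  expect_equal(nrow(res$display_list), 1)
  expect_error(apply_user_action(st, "Shout"), "unknown user action")
})

test_that("latching alarms keep sounding after the condition ends until silenced", {
  st <- monitor_state(active_alarms("Asystole", 3L, onset_ts = now0))
  st <- end_condition(st, 1L)
  res <- state_announce(st, now0 + 30)
  expect_equal(nrow(res$announced), 1) # still active and audible
  expect_true(res$announced$audible)
  st <- apply_user_action(st, "Silence", now = now0 + 40)
  st <- end_condition(st, 1L)
  expect_equal(nrow(st$active), 0)
})

test_that("non-latching alarms reset when the condition ends", {
  st <- monitor_state(active_alarms("SpO2", 2L, onset_ts = now0))
  st <- end_condition(st, 1L)
  expect_equal(nrow(st$active), 0)
})

test_that("pause suppresses audio for its duration; infinite pause needs Resume", {
  st <- monitor_state(active_alarms("HR", 2L, onset_ts = now0))
  st <- apply_user_action(st, "Pause", now = now0, duration_s = 120)
  expect_false(state_announce(st, now0 + 60)$announced$audible)
  expect_true(state_announce(st, now0 + 180)$announced$audible)

  st <- apply_user_action(st, "Pause", now = now0, duration_s = Inf)
  expect_false(state_announce(st, now0 + 1e6)$announced$audible)
  st <- apply_user_action(st, "Resume", now = now0 + 1e6)
  expect_true(state_announce(st, now0 + 1e6 + 1)$announced$audible)
})

test_that("yellow-only pause configuration keeps red alarms audible", {
  st <- monitor_state(active_alarms(c("Desat", "HR"), c(3L, 2L),
                                    onset_ts = now0 + c(0, 5)),
                      yellow_pause_only = TRUE)
  st <- apply_user_action(st, "Pause", now = now0 + 10, duration_s = Inf)
  res <- state_announce(st, now0 + 20)
  expect_equal(res$announced$parameter, "Desat")
  expect_true(res$announced$audible)
})

test_that("scenario runner emits a parseable event stream and a trace", {
  scen <- tibble::tibble(
    timestamp = c("4/20/14 1:00:00", "4/20/14 1:00:30", "4/20/14 1:01:00",
                  "4/20/14 1:02:00"),
    kind = c("onset", "onset", "action", "end"),
    parameter = c("Pair PVCs", "Pause", NA, "Pause"),
    priority_level = c(2L, 1L, NA, 1L),
    action = c(NA, NA, "Silence", NA))
  res <- run_scenario(scen)
  expect_equal(res$trace$announced[2], "Pair PVCs") # Pause suppressed
  expect_false(res$trace$audible[3]) # silenced
  ev <- parse_events(res$records)
  expect_true(all(ev$event_type != "unparsed"))
})
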