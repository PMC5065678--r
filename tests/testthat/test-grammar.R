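# worked examples from real unit audit-log messages
test_that("numerical physiologic alarms parse priority, value, limit, direction", {
  cases <- tibble::tribble(
    ~msg,                            ~level, ~color,    ~param,  ~value, ~limit, ~dir,    ~status,
    "**PAPd 18 >16 Generated.",          2L, "yellow",  "PAPd",      18,     16, "above", "generated",
    "**PAPd 18 >16 Ended.",              2L, "yellow",  "PAPd",      18,     16, "above", "ended",
    "**ABPs 170 >160 Generated.",        2L, "yellow",  "ABPs",     170,    160, "above", "generated",
    "**ABPs 168 >160 Ended.",            2L, "yellow",  "ABPs",     168,    160, "above", "ended",
    "***Desat 70 < 78 Generated.",       3L, "red",     "Desat",     70,     78, "below", "generated",
    "***Desat 73 < 78 ended.",           3L, "red",     "Desat",     73,     78, "below", "ended",
    "*** Desat 44 < 50 Generated.",      3L, "red",     "Desat",     44,     50, "below", "generated",
    "*** Desat 89 < 90 Generated.",      3L, "red",     "Desat",     89,     90, "below", "generated",
    "**RR 37 >30 Ended.",                2L, "yellow",  "RR",        37,     30, "above", "ended",
    "*HR 153>150 Generated.",            1L, "advisory", "HR",       153,    150, "above", "generated",
    "**HR 153 >150 Generated.",          2L, "yellow",  "HR",       153,    150, "above", "generated"
  )
  got <- parse_messages(cases$msg)
  expect_true(all(got$event_type == "physiologic"))
  expect_true(all(got$measurement_kind == "numerical"))
  expect_identical(got$priority_level, cases$level)
  expect_identical(got$color, cases$color)
  expect_identical(got$parameter, cases$param)
  expect_identical(got$value, cases$value)
  expect_identical(got$limit, cases$limit)
  expect_identical(got$direction, cases$dir)
  expect_identical(got$status, cases$status)
})

test_that("categorical alarms carry no value, limit or direction", {
  got <- parse_message("*Multiform PVCs Generated.")
  expect_equal(got$event_type, "physiologic")
  expect_equal(got$priority_level, 1L)
  expect_equal(got$color, "advisory")
  expect_equal(got$parameter, "Multiform PVCs")
  expect_equal(got$measurement_kind, "categorical")
  expect_true(is.na(got$value) && is.na(got$limit))
})

test_that("technical INOPs parse at soft, moderate and hard levels", {
  got <- parse_messages(c("ECG Leads Off Generated.", "ECG Leads Off Ended.",
                          "!!Batt Empty Generated.", "!!!Check Equipment Generated."))
  expect_true(all(got$event_type == "technical"))
  expect_identical(got$priority_level, c(0L, 0L, 2L, 3L))
  expect_identical(got$parameter, c("ECG Leads Off", "ECG Leads Off",
                                    "Batt Empty", "Check Equipment"))
  expect_identical(got$status, c("generated", "ended", "generated", "generated"))
})

test_that("sound events parse by kind", {
  got <- parse_messages(c("Yellow alarm sound played.", "Red alarm sound played.",
                          "INOP sound played."))
  expect_true(all(got$event_type == "sound"))
  expect_identical(got$sound_kind, c("yellow", "red", "inop"))
})

test_that("user actions map onto the action taxonomy", {
  cases <- tibble::tribble(
    ~msg,                                          ~kind,
    "Silence.",                                    "Silence",
    "Resume All Alarms.",                          "Resume All Alarms",
    "Pause All Alarms.",                           "Pause All Alarms",
    "Patient transferred to 9035-S1.",             "Transfer",
    "Patient category set to Adult.",              "Patient Category Changed",
    "Pacer algorithm set to Pacer Algorithm On.",  "Paced Status Changed",
    "Equipment Offline.",                          "Equipment Offline",
    "Equipment Online.",                           "Equipment Online",
    "Arrhythmia Off.",                             "Measurement Off",
    "Arrhy: Missed Beat Off.",                     "Alarm Off"
  )
  got <- parse_messages(cases$msg)
  expect_true(all(got$event_type == "action"))
  expect_identical(got$action_kind, cases$kind)
  reg <- default_registry()
  expect_true(all(got$action_kind %in% reg$actions))
})

test_that("alarm-limit changes extract bounds with sign preserved", {
  one <- parse_limit_change("SpO_2_: Desat Limit 78.")
  expect_equal(one$action_kind, "Alarm Limit Change")
  expect_equal(one$limit_param, "Desat")
  expect_equal(one$limit_low, 78)
  expect_true(is.na(one$limit_high))

  two <- parse_limit_change("ST: Al. Limits ST-V2 High: 1.6 ST-V2 Low: −1.6.")
  expect_equal(two$limit_param, "ST-V2")
  expect_equal(two$limit_high, 1.6)
  expect_equal(two$limit_low, -1.6)

  off <- parse_limit_change("Arrhy: Missed Beat Off.")
  expect_equal(off$event_type, "unparsed") # no numeric bound: not a limit change
  expect_equal(parse_message("Arrhy: Missed Beat Off.")$action_kind, "Alarm Off")
})

test_that("the three apnea display forms classify as documented", {
  plain <- parse_message("***Apnea Generated.")
  expect_equal(plain$measurement_kind, "categorical")
  timed <- parse_message("***Apnea 0:25 Generated.")
  expect_equal(timed$measurement_kind, "numerical")
  expect_equal(timed$apnea_seconds, 25)
  long <- parse_message("***Apnea 2:05 Generated.")
  expect_equal(long$apnea_seconds, 125)
  flag <- parse_message("***Apnea > 20 sec Generated.")
  expect_true(flag$apnea_gt20)
  expect_true(is.na(flag$limit)) # the "> 20 sec" text is not a limit comparison
})

test_that("every fixture message parses to a non-unparsed variant", {
  for (ev in list(unit_log_events(), desat_limit_events())) {
    expect_true(all(ev$event_type != "unparsed"))
  }
})

test_that("unrecognized messages come back as unparsed, never dropped or errored", {
  got <- parse_messages(c("Gibberish nobody prints", "Silence."))
  expect_identical(got$event_type, c("unparsed", "action"))
  expect_equal(got$raw_message[1], "Gibberish nobody prints")
})

test_that("no message is both numerical and categorical", {
  msgs <- c("**PAPd 18 >16 Generated.", "*Multiform PVCs Generated.",
            "***Apnea Generated.", "***Apnea 0:25 Generated.",
            "***Apnea > 20 sec Generated.", "ECG Leads Off Generated.")
  got <- parse_messages(msgs)
  expect_true(all(got$measurement_kind %in% c("numerical", "categorical")))
  # numerical alarms other than the special apnea displays carry all three
  num <- got[got$measurement_kind == "numerical" & got$parameter != "Apnea", ]
  expect_true(all(!is.na(num$value) & !is.na(num$limit) &
                    num$direction %in% c("above", "below")))
  cat_ <- got[got$measurement_kind == "categorical", ]
  expect_true(all(is.na(cat_$value) & is.na(cat_$limit)))
})

test_that("rendering a parsed alarm reproduces its priority marks", {
  msgs <- c("**PAPd 18 >16 Generated.", "***Desat 70 < 78 Generated.",
            "*Multiform PVCs Generated.", "**HR 153 >150 Generated.",
            "!!Batt Empty Generated.", "***Apnea 0:25 Generated.")
  for (m in msgs) {
    ev <- parse_message(m)
    rendered <- format_alarm(ev)
    n_marks <- function(s) nchar(stringr::str_match(s, "^(\\*+|!+)")[, 1])
    expect_equal(n_marks(rendered), n_marks(m), info = m)
    # rendering then reparsing is the identity on the parsed fields
    again <- parse_message(rendered)
    expect_equal(again$priority_level, ev$priority_level, info = m)
    expect_equal(again$parameter, ev$parameter, info = m)
    expect_equal(again$value, ev$value, info = m)
    expect_equal(again$limit, ev$limit, info = m)
  }
})

test_that("unknown parameters parse generically (open vocabulary)", {
  got <- parse_message("**Xyz27 42 >40 Generated.")
  expect_equal(got$parameter, "Xyz27")
  expect_equal(got$value, 42)
})
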